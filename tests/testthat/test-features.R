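test_that("Haralick features of a constant region hit their closed forms", {
  img <- matrix(5, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  h <- haralick_features(img, mask)
  expect_length(h, 28)
  expect_equal(unname(h["har_asm_mean"]), 1)
  expect_equal(unname(h["har_contrast_mean"]), 0)
  expect_equal(unname(h["har_contrast_range"]), 0)
})

test_that("GLCM entries match brute-force pair enumeration", {
  # 4x4 checkerboard of two grey levels
  img <- matrix(rep(c(0, 1), 8), 4, 4)
  img[, c(2, 4)] <- 1 - img[, c(2, 4)]
  mask <- matrix(TRUE, 4, 4)
  q <- cfichill:::.quantize_gray(img, mask, 32L)
  for (off in cfichill:::.GLCM_OFFSETS) {
    P <- cfichill:::.glcm(q, off, 32L)
    # oracle: explicit double loop over all pixel pairs
    C <- matrix(0, 32, 32)
    for (i in 1:4) for (j in 1:4) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 >= 1 && i2 <= 4 && j2 >= 1 && j2 <= 4) {
        a <- q[i, j]; b <- q[i2, j2]
        C[a, b] <- C[a, b] + 1
        C[b, a] <- C[b, a] + 1
      }
    }
    expect_equal(P, C / sum(C))
    # GLCM structural invariants
    expect_equal(P, t(P))
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1)
  }
  # contrast for the horizontal offset: all 24 symmetric pairs differ by
  # 31 quantized levels
  st <- cfichill:::.haralick_stats(cfichill:::.glcm(q, c(0L, 1L), 32L))
  expect_equal(st[2], 31^2)
})

test_that("co-occurring pairs are restricted to the mask", {
  img <- matrix(c(1, 1, 5, 5), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  q <- cfichill:::.quantize_gray(img, mask, 32L)
  P <- cfichill:::.glcm(q, c(1L, 0L), 32L)  # vertical pairs within column 1
  expect_equal(sum(P), 1)
  expect_equal(P[1, 1], 1)  # only the (1,1)-(2,1) pair, both level 1
  expect_error(haralick_features(img, matrix(c(TRUE, rep(FALSE, 3)), 2, 2)),
               "mask too small")
})

test_that("uniform LBP histogram matches direct bit-pattern enumeration", {
  c0 <- lbp_features(matrix(3, 8, 8), matrix(TRUE, 8, 8))
  expect_length(c0, 59)
  expect_equal(sum(c0), 1)
  expect_equal(unname(c0["lbp_p000"]), 1)  # no neighbour is brighter

  set.seed(42)
  img <- matrix(runif(100), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  got <- lbp_features(img, mask)
  # oracle: per-pixel code by explicit loops, same neighbour order
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  ucodes <- cfichill:::.uniform_codes()
  h <- numeric(59)
  for (i in 2:9) for (j in 2:9) {
    code <- 0
    for (k in 1:8)
      if (img[i + offs[[k]][1], j + offs[[k]][2]] > img[i, j])
        code <- code + 2^(k - 1)
    b <- match(code, ucodes, nomatch = 59)
    h[b] <- h[b] + 1
  }
  expect_equal(unname(got), h / sum(h))
})

test_that("a single bright pixel produces the expected uniform patterns", {
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  h <- lbp_features(img, matrix(TRUE, 5, 5))
  # the 8 neighbours of the bright pixel each see exactly one brighter
  # neighbour: 8 single-bit (uniform) patterns, one centre sees none
  # brighter (pattern 0), remaining centres see pattern 0 too
  expect_equal(sum(h), 1)
  single_bit <- paste0("lbp_p", sprintf("%03d", 2^(0:7)))
  expect_equal(unname(sum(h[single_bit])), 8 / 9)
  expect_equal(unname(h["lbp_p000"]), 1 / 9)
})

test_that("Gabor features vanish on constant input and peak at the matched grating", {
  g0 <- gabor_features(matrix(4, 48, 48), matrix(TRUE, 48, 48))
  expect_length(g0, 67)
  expect_lt(max(abs(g0)), 1e-8)

  n <- 64
  freqs <- c(0.05, 0.1, 0.2, 0.4)
  theta <- 2 * pi / 8  # orientation index 3 of 8
  xr <- outer(1:n, 1:n, function(y, x) x * cos(theta) + y * sin(theta))
  grating <- sin(2 * pi * 0.2 * xr)
  g <- gabor_features(grating, matrix(TRUE, n, n), frequencies = freqs)
  means <- g[grepl("^gab_f[0-9]o[0-9]_mean$", names(g))]
  expect_identical(names(which.max(means)), "gab_f3o3_mean")
})

test_that("intensity features reproduce closed-form moments", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  v <- intensity_features(img, matrix(TRUE, 2, 2))
  expect_equal(unname(v),
               c(2.5, sqrt(1.25), 1, 4, 0, 2.5625 / 1.5625 - 3))
  const <- intensity_features(matrix(1, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(unname(const), c(1, 0, 1, 1, 0, 0))
})

test_that("Hu moments are invariant to rotation and translation", {
  set.seed(5)
  img <- matrix(0, 40, 40)
  img[10:25, 8:20] <- runif(16 * 13, 0.5, 1)
  mask <- img > 0
  h0 <- hu_moments(img, mask)
  rot <- t(img)[, 40:1]  # 90-degree rotation
  expect_equal(hu_moments(rot, t(mask)[, 40:1]), h0, tolerance = 1e-6)
  tr <- matrix(0, 40, 40); tr[15:30, 15:27] <- img[10:25, 8:20]
  trm <- matrix(FALSE, 40, 40); trm[15:30, 15:27] <- mask[10:25, 8:20]
  expect_equal(hu_moments(tr, trm), h0, tolerance = 1e-8)
})

test_that("Hu moments match a brute-force double-sum oracle", {
  # off-centre disk with an intensity ramp so no invariant degenerates
  n <- 32
  d2 <- outer((1:n - 14)^2, (1:n - 17)^2, "+")
  img <- (d2 <= 8^2) * rep(seq(0.5, 1.5, length.out = n), each = n)
  mask <- img > 0
  got <- hu_moments(img, mask)
  # oracle: explicit loops over pixels for the defining moment sums
  m00 <- 0; mx <- 0; my <- 0
  for (i in 1:n) for (j in 1:n) {
    m00 <- m00 + img[i, j]; mx <- mx + j * img[i, j]; my <- my + i * img[i, j]
  }
  xb <- mx / m00; yb <- my / m00
  mu <- matrix(0, 4, 4)
  for (i in 1:n) for (j in 1:n)
    for (p in 0:3) for (q in 0:3)
      mu[p + 1, q + 1] <- mu[p + 1, q + 1] +
        (j - xb)^p * (i - yb)^q * img[i, j]
  eta <- function(p, q) mu[p + 1, q + 1] / m00^(1 + (p + q) / 2)
  phi1 <- eta(2, 0) + eta(0, 2)
  phi2 <- (eta(2, 0) - eta(0, 2))^2 + 4 * eta(1, 1)^2
  expect_equal(unname(got["hu1"]), -sign(phi1) * log10(abs(phi1)))
  expect_equal(unname(got["hu2"]), -sign(phi2) * log10(abs(phi2)))
})

test_that("the per-band vector has the contracted 167-feature layout", {
  s <- tiny_sample(1, seed = 14)
  m <- segment_fruit(s$image_750)$mask
  corr <- correct_vignetting(bemd_decompose(s$image_750))
  v <- extract_features(corr, m, "750")
  expect_length(v, 167)
  groups <- c(har = 28, lbp = 59, gab = 67, int = 6, hu = 7)
  got <- table(sub("^(har|lbp|gab|int|hu).*", "\\1", names(v)))
  expect_equal(as.integer(got[names(groups)]), unname(groups))
  expect_true(all(endsWith(names(v), "_750")))
  expect_identical(v, extract_features(corr, m, "750"))  # deterministic

  v675 <- extract_features(corr, m, "675")
  fused <- fuse_features(v675, v)
  expect_length(fused, 334)
  expect_true(all(endsWith(names(fused)[1:167], "_675")))
  expect_identical(fused[endsWith(names(fused), "_675")], c(v675))
  expect_identical(fused[endsWith(names(fused), "_750")], c(v))
  expect_error(fuse_features(v, v675), "675-band")
  expect_error(fuse_features(v675, v675), "675-band")
})

test_that("normalisation fits on training rows only", {
  x <- matrix(c(1, 2, 3, 10, 20, 30, 5, 5, 5), 3, 3)
  colnames(x) <- c("a", "b", "c")
  expect_warning(out <- normalize_features(x, 1:3), "zero-variance")
  expect_equal(colMeans(out[, 1:2]), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(out[, 1:2], 2, var), c(a = 1, b = 1), tolerance = 1e-10)
  expect_true(all(out[, 3] == 0))
  # manual oracle on a 3-row toy table, test row = training mean
  x2 <- rbind(x[, 1:2], c(2, 20))
  got <- normalize_features(x2, 1:3)
  expect_equal(got[4, ], c(a = 0, b = 0))
  expect_equal(unname(got[1, "a"]), (1 - 2) / 1)
  expect_error(normalize_features(x, 1), "at least 2")
})

test_that("mean intensity separates extreme classes without overlap", {
  # noise-free scenes carry no oscillatory content, so the sanity check
  # runs on the masked raw band where the lesion contrast lives in full
  m0 <- m2 <- numeric(3)
  for (i in 1:3) {
    s0 <- tiny_sample(0, seed = 60 + i, image_size = 128, noise_sd = 0)
    s2 <- tiny_sample(2, seed = 60 + i, image_size = 128, noise_sd = 0,
                      lesion_darkening = 0.5)
    f <- function(s) {
      msk <- segment_fruit(s$image_750)$mask
      intensity_features(s$image_750, msk)["int_mean"]
    }
    m0[i] <- f(s0); m2[i] <- f(s2)
  }
  expect_gt(min(m0), max(m2))
})
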