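# Per-band feature extraction: 28 Haralick + 59 uniform-LBP + 67 Gabor +
# 6 intensity + 7 Hu moments = 167 features; dual-band fusion gives 334.
# Inputs are vignetting-corrected (dimensionless) images plus the fruit mask.

.HARALICK_STATS <- c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "diff_variance", "diff_entropy", "imc1", "imc2", "mcc")

.GLCM_OFFSETS <- list(d0 = c(0L, 1L), d45 = c(-1L, 1L),
                      d90 = c(-1L, 0L), d135 = c(-1L, -1L))

# quantize in-mask intensities to `levels` grey levels by linear rescaling
# of the in-mask range; pixels outside the mask become NA
.quantize_gray <- function(image, mask, levels = 32L) {
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  vals <- image[mask]
  rng <- range(vals)
  q[mask] <- if (rng[2] > rng[1])
    pmin(as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * levels)) + 1L,
         levels) else 1L
  q
}

# symmetric, normalized grey-level co-occurrence matrix for one offset;
# only pairs with both pixels inside the mask are counted
.glcm <- function(q, offset, levels = 32L) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- seq(max(1, 1 - dr), min(nr, nr - dr))
  c1 <- seq(max(1, 1 - dc), min(nc, nc - dc))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  counts <- tabulate((a[keep] - 1L) * levels + b[keep], nbins = levels^2)
  P <- matrix(counts, levels, levels)   # P[b, a]; symmetrized next
  P <- P + t(P)
  P / sum(P)
}

# the 14 Haralick (1973) statistics of one normalized symmetric GLCM.
# Sum variance is computed about the sum average (the printed formula's
# use of sum entropy is a known erratum). Natural logarithms throughout;
# degenerate denominators yield 0 by convention.
.haralick_stats <- function(P) {
  G <- nrow(P)
  lv <- seq_len(G)
  I <- matrix(lv, G, G); J <- t(I)
  px <- rowSums(P)                       # == colSums(P) by symmetry
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)
  asm <- sum(P^2)
  contrast <- sum((I - J)^2 * P)
  correlation <- if (sig2 > 1e-12) (sum(I * J * P) - mu^2) / sig2 else 0
  idm <- sum(P / (1 + (I - J)^2))
  psum <- as.vector(rowsum(as.vector(P), as.vector(I + J)))
  ksum <- sort(unique(as.vector(I + J)))
  sum_avg <- sum(ksum * psum)
  sum_var <- sum((ksum - sum_avg)^2 * psum)
  sum_ent <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  pdiff <- as.vector(rowsum(as.vector(P), as.vector(abs(I - J))))
  kdiff <- sort(unique(as.vector(abs(I - J))))
  dmu <- sum(kdiff * pdiff)
  diff_var <- sum((kdiff - dmu)^2 * pdiff)
  diff_ent <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  pp <- outer(px, px)
  hxy1 <- -sum(P[pp > 0] * log(pp[pp > 0]))
  hxy2 <- -sum(pp[pp > 0] * log(pp[pp > 0]))
  imc1 <- if (hx > 1e-12) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))
  mcc <- tryCatch({
    nz <- which(px > 0)
    if (length(nz) < 2) 0 else {
      Pn <- P[nz, nz, drop = FALSE]
      # Q[i,j] = sum_k p(i,k) p(j,k) / (px(i) py(k)); py == px by symmetry
      Q <- (Pn / px[nz]) %*% t(sweep(Pn, 2, px[nz], "/"))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(pmax(0, ev[2]))
    }
  }, error = function(e) 0)
  c(asm, contrast, correlation, sig2, idm, sum_avg, sum_var, sum_ent,
    entropy, diff_var, diff_ent, imc1, imc2, mcc)
}

#' Haralick texture features (28 values)
#'
#' Grey-level co-occurrence matrices at distance 1 for the four offsets
#' 0/45/90/135 degrees, symmetrised and normalised, after quantising the
#' in-mask intensity range to `levels` grey levels. The 14 Haralick
#' statistics are computed per offset and summarised by their mean and
#' range across the four offsets, giving 28 values in a fixed order
#' (14 means, then 14 ranges).
#'
#' @param image Numeric matrix (typically a vignetting-corrected image).
#' @param mask Logical fruit mask; co-occurring pairs must have both
#'   pixels inside the mask.
#' @param levels Number of grey levels for quantisation.
#' @return Named numeric vector of length 28.
#' @export
haralick_features <- function(image, mask, levels = 32L) {
  .check_image(image); .check_mask(mask, image)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  q <- .quantize_gray(image, mask, levels)
  stats <- sapply(.GLCM_OFFSETS, function(off) {
    P <- .glcm(q, off, levels)
    if (is.null(P))
      stop("mask too small: no co-occurring in-mask pixel pair",
           call. = FALSE)
    .haralick_stats(P)
  })
  out <- c(rowMeans(stats), apply(stats, 1, max) - apply(stats, 1, min))
  names(out) <- paste0("har_", rep(.HARALICK_STATS, 2), "_",
                       rep(c("mean", "range"), each = 14))
  out
}

# codes 0..255 with at most 2 circular 0/1 transitions, ascending
.uniform_codes <- function() {
  codes <- 0:255
  bits <- t(sapply(codes, function(x) as.integer(intToBits(x))[1:8]))
  trans <- rowSums(bits != bits[, c(2:8, 1)])
  codes[trans <= 2]
}

#' Uniform local binary pattern features (59 values)
#'
#' LBP with 8 neighbours on the 3x3 square neighbourhood: each neighbour
#' strictly brighter than the centre contributes its bit. The 58 uniform
#' patterns (at most two circular transitions) get one bin each, all
#' remaining patterns share one pooled bin; the histogram is taken over
#' centre pixels whose full 3x3 neighbourhood lies inside the mask and is
#' normalised to sum 1. A constant image therefore puts all mass in the
#' all-zeros pattern bin.
#'
#' @inheritParams haralick_features
#' @return Named numeric vector of length 59 summing to 1.
#' @export
lbp_features <- function(image, mask) {
  .check_image(image); .check_mask(mask, image)
  if (sum(mask) < 9) stop("mask must cover at least 9 pixels", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- image[ri, ci]
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- matrix(0L, nrow(ctr), ncol(ctr))
  valid <- mask[ri, ci]
  for (k in seq_along(offs)) {
    nb <- image[ri + offs[[k]][1], ci + offs[[k]][2]]
    code <- code + (nb > ctr) * 2L^(k - 1L)
    valid <- valid & mask[ri + offs[[k]][1], ci + offs[[k]][2]]
  }
  if (!any(valid))
    stop("no centre pixel has its full 3x3 neighbourhood inside the mask",
         call. = FALSE)
  ucodes <- .uniform_codes()
  bin <- match(code[valid], ucodes, nomatch = 59L)
  h <- tabulate(bin, nbins = 59L)
  h <- h / sum(h)
  names(h) <- c(paste0("lbp_p", sprintf("%03d", ucodes)), "lbp_other")
  h
}

# --- Gabor bank -------------------------------------------------------

# complex, zero-DC, unit-energy Gabor kernel
.gabor_kernel <- function(freq, theta, max_half = Inf) {
  sigma <- 0.56 / freq
  hs <- min(ceiling(3 * sigma), max_half)
  g <- seq(-hs, hs)
  X <- matrix(rep(g, each = length(g)), length(g))  # column offset
  Y <- t(X)                                          # row offset
  xr <- X * cos(theta) + Y * sin(theta)
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  kern <- env * exp(2i * pi * freq * xr)
  re <- Re(kern) - env * sum(Re(kern)) / sum(env)   # remove DC response
  kern <- re + 1i * Im(kern)
  kern / sqrt(sum(Mod(kern)^2))
}

.gabor_cache <- new.env(parent = emptyenv())

# FFTs of the whole bank, embedded (wrapped-centred) in a padded frame
.gabor_bank_fft <- function(pdim, frequencies, n_orient, max_half) {
  key <- paste(c(pdim, signif(frequencies, 8), n_orient, max_half),
               collapse = "|")
  if (!is.null(.gabor_cache[[key]])) return(.gabor_cache[[key]])
  bank <- list()
  for (fi in seq_along(frequencies)) {
    for (oi in seq_len(n_orient)) {
      kern <- .gabor_kernel(frequencies[fi], (oi - 1) * pi / n_orient,
                            max_half)
      hs <- (nrow(kern) - 1) / 2
      K <- matrix(0 + 0i, pdim[1], pdim[2])
      ridx <- ((-hs:hs) %% pdim[1]) + 1
      cidx <- ((-hs:hs) %% pdim[2]) + 1
      K[ridx, cidx] <- kern
      bank[[paste0("f", fi, "o", oi)]] <- Conj(fft(K))
    }
  }
  .gabor_cache[[key]] <- bank
  bank
}

#' Gabor texture features (67 values)
#'
#' A bank of 4 frequencies (geometric, 0.05 to 0.4 cycles/pixel) by 8
#' orientations gives 32 zero-DC, unit-energy complex Gabor filters.
#' Responses are computed by FFT correlation with reflective padding; per
#' filter, the mean and standard deviation of the response magnitude over
#' the mask give 64 values, plus three bank-level aggregates: the global
#' mean and standard deviation of all in-mask magnitudes, and the mean
#' per-pixel total bank energy (sum of squared magnitudes over filters,
#' averaged over in-mask pixels).
#'
#' @inheritParams haralick_features
#' @param frequencies Filter frequencies in cycles/pixel.
#' @param n_orient Number of orientations spanning half a turn.
#' @return Named numeric vector of length 67.
#' @export
gabor_features <- function(image, mask, frequencies = c(0.05, 0.1, 0.2, 0.4),
                           n_orient = 8L) {
  .check_image(image); .check_mask(mask, image)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  max_half <- max(4L, floor((min(dim(image)) - 1) / 2))
  hs_max <- min(ceiling(3 * 0.56 / min(frequencies)), max_half)
  pad <- .pad_reflect(image, hs_max)
  Fimg <- fft(pad$m)
  bank <- .gabor_bank_fft(dim(pad$m), frequencies, n_orient, max_half)
  npix_pad <- prod(dim(pad$m))
  inmask <- which(mask)
  nfilt <- length(bank)
  out <- numeric(2 * nfilt + 3)
  nm <- character(2 * nfilt + 3)
  all_sum <- all_sum2 <- 0
  energy <- numeric(length(inmask))
  for (b in seq_len(nfilt)) {
    resp <- fft(Fimg * bank[[b]], inverse = TRUE) / npix_pad
    mag <- Mod(.crop(resp, pad$p, nrow(image), ncol(image)))[inmask]
    out[2 * b - 1] <- mean(mag)
    out[2 * b] <- sd_pop(mag)
    nm[2 * b - 1] <- paste0("gab_", names(bank)[b], "_mean")
    nm[2 * b] <- paste0("gab_", names(bank)[b], "_sd")
    all_sum <- all_sum + sum(mag)
    all_sum2 <- all_sum2 + sum(mag^2)
    energy <- energy + mag^2
  }
  ntot <- nfilt * length(inmask)
  gmean <- all_sum / ntot
  gsd <- sqrt(pmax(0, all_sum2 / ntot - gmean^2))
  out[2 * nfilt + 1:3] <- c(gmean, gsd, mean(energy))
  nm[2 * nfilt + 1:3] <- c("gab_mean", "gab_sd", "gab_energy")
  names(out) <- nm
  out
}

# population standard deviation (divisor n)
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Basic intensity features (6 values)
#'
#' Mean, population standard deviation, minimum, maximum, skewness and
#' excess kurtosis of the in-mask intensities, in that order. For a
#' degenerate (constant) distribution skewness and kurtosis are defined
#' as 0.
#'
#' @inheritParams haralick_features
#' @return Named numeric vector of length 6.
#' @export
intensity_features <- function(image, mask) {
  .check_image(image); .check_mask(mask, image)
  v <- image[mask]
  if (length(v) < 2) stop("mask must cover at least 2 pixels", call. = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 1e-300) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  } else skew <- kurt <- 0
  c(int_mean = m, int_sd = sqrt(m2), int_min = min(v), int_max = max(v),
    int_skew = skew, int_kurt = kurt)
}

#' Hu invariant moments (7 values)
#'
#' The seven Hu moment invariants of the masked intensity image (pixels
#' outside the mask weigh zero), which are invariant to translation,
#' scale and in-plane rotation. A sign-preserving log-magnitude transform
#' `-sign(h) * log10(|h|)` conditions the wide dynamic range; exact zeros
#' map to 0.
#'
#' @inheritParams haralick_features
#' @return Named numeric vector of length 7 (`hu1`..`hu7`).
#' @export
hu_moments <- function(image, mask) {
  .check_image(image); .check_mask(mask, image)
  f <- image
  f[!mask] <- 0
  s <- sum(f)
  if (s <= 0) stop("zero total intensity inside the mask", call. = FALSE)
  xs <- col(f); ys <- row(f)
  xb <- sum(xs * f) / s; yb <- sum(ys * f) / s
  dx <- xs - xb; dy <- ys - yb
  mu <- function(p, q) sum(dx^p * dy^q * f)
  eta <- function(p, q) mu(p, q) / s^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- c(n20 + n02,
         (n20 - n02)^2 + 4 * n11^2,
         (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
         (n30 + n12)^2 + (n21 + n03)^2,
         (n30 - 3 * n12) * (n30 + n12) *
           ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
           (3 * n21 - n03) * (n21 + n03) *
           (3 * (n30 + n12)^2 - (n21 + n03)^2),
         (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
           4 * n11 * (n30 + n12) * (n21 + n03),
         (3 * n21 - n03) * (n30 + n12) *
           ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
           (n30 - 3 * n12) * (n21 + n03) *
           (3 * (n30 + n12)^2 - (n21 + n03)^2))
  out <- ifelse(abs(h) < 1e-300, 0, -sign(h) * log10(abs(h)))
  names(out) <- paste0("hu", 1:7)
  out
}

#' Extract the complete 167-feature vector for one band
#'
#' Concatenates [haralick_features()] (28), [lbp_features()] (59),
#' [gabor_features()] (67), [intensity_features()] (6) and [hu_moments()]
#' (7) in that order and appends the band tag to every feature name.
#'
#' @inheritParams haralick_features
#' @param band Band label, `"675"` or `"750"`.
#' @return Named numeric vector of length 167 with attribute `band`.
#' @export
extract_features <- function(image, mask, band = c("750", "675")) {
  band <- match.arg(band)
  v <- c(haralick_features(image, mask), lbp_features(image, mask),
         gabor_features(image, mask), intensity_features(image, mask),
         hu_moments(image, mask))
  stopifnot(length(v) == 167L)
  if (!all(is.finite(v)))
    stop("non-finite feature values: ",
         paste(head(names(v)[!is.finite(v)], 5), collapse = ", "),
         call. = FALSE)
  names(v) <- paste0(names(v), "_", band)
  attr(v, "band") <- band
  v
}

#' Fuse the two single-band feature vectors
#'
#' Concatenation with the 675 nm block first, yielding 334 named values.
#'
#' @param v675,v750 Single-band vectors from [extract_features()].
#' @return Named numeric vector of length 334 with attribute
#'   `band = "fused"`.
#' @export
fuse_features <- function(v675, v750) {
  b1 <- attr(v675, "band"); b2 <- attr(v750, "band")
  if (!identical(b1, "675") || !identical(b2, "750"))
    stop("fuse_features() needs one 675-band and one 750-band vector, ",
         "in that order", call. = FALSE)
  out <- c(v675, v750)
  stopifnot(length(out) == 334L)
  attr(out, "band") <- "fused"
  out
}
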