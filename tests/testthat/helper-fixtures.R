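# Small scene defaults used throughout the tests: geometry scales with
# image_size, so a 96 px frame renders the same physical scene as the
# 512 px default, just coarser (and much faster).

tiny_params <- function(image_size = 96, seed = 1L, ...) {
  scene_params(image_size = image_size, seed = seed, ...)
}

tiny_sample <- function(label = 0, seed = 1L, ...) {
  generate_sample(tiny_params(seed = seed, ...), label)
}

# brute-force perpendicular point-to-line distance scan over histogram
# bins, the independent oracle for the Rosin construction
rosin_scan <- function(counts, mids, peak, last) {
  p1 <- c(mids[peak], counts[peak])
  p2 <- c(mids[last], counts[last])
  len <- sqrt(sum((p2 - p1)^2))
  best <- -Inf; best_i <- NA
  for (i in seq(peak + 1, last)) {
    d <- abs((p2[1] - p1[1]) * (counts[i] - p1[2]) -
               (mids[i] - p1[1]) * (p2[2] - p1[2])) / len
    if (d > best + 1e-12) { best <- d; best_i <- i }
  }
  mids[best_i] + (mids[2] - mids[1]) / 2
}

# random unimodal histogram: steep rise to a low-intensity mode, then a
# decaying convex tail, mimicking a dark background plus bright object
random_unimodal_hist <- function(seed, bins = 120) {
  set.seed(seed)
  peak <- sample(3:12, 1)
  tail_len <- sample(40:(bins - peak - 5), 1)
  rise <- round(seq(5, 1000, length.out = peak) + runif(peak, 0, 30))
  decay <- round(1000 * exp(-seq_len(tail_len) / runif(1, 4, 25)) +
                   runif(tail_len, 0, 8))
  counts <- c(rise, decay, rep(0, bins - peak - tail_len))
  list(counts = counts, mids = seq(0.5, by = 1, length.out = bins))
}

cv_of <- function(v) stats::sd(v) / mean(v)
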