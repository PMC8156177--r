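#' Configuration for bi-dimensional empirical mode decomposition
#'
#' @param n Number of intrinsic mode function (IMF) images to extract.
#' @param k Upper IMF index used in the vignetting-correction
#'   reconstruction; must satisfy `1 <= k < n`.
#' @param max_sift_iterations Cap on sifting iterations per IMF.
#' @param sift_tolerance Sifting stops once the envelope-mean energy
#'   relative to the current mode energy falls below this value.
#' @param envelope_window Extrema-neighbourhood radius (pixels) for the
#'   first IMF; the window doubles for each successive IMF (capped at an
#'   eighth of the shorter image side) to enforce scale separation.
#' @param residual_floor Division guard for the reconstruction, expressed
#'   as a fraction of the source-image maximum: the residual is clamped at
#'   `residual_floor * max(image)` before dividing.
#' @return An object of class `bemd_config`.
#' @export
bemd_config <- function(n = 6L, k = 3L, max_sift_iterations = 8L,
                        sift_tolerance = 1e-3, envelope_window = 4L,
                        residual_floor = 1e-6) {
  cfg <- list(n = as.integer(n), k = as.integer(k),
              max_sift_iterations = as.integer(max_sift_iterations),
              sift_tolerance = sift_tolerance,
              envelope_window = as.integer(envelope_window),
              residual_floor = residual_floor)
  if (cfg$k < 1 || cfg$k >= cfg$n)
    stop("reconstruction index must satisfy 1 <= k < n", call. = FALSE)
  if (cfg$max_sift_iterations < 1)
    stop("max_sift_iterations must be >= 1", call. = FALSE)
  if (cfg$residual_floor <= 0)
    stop("residual_floor must be > 0", call. = FALSE)
  if (cfg$envelope_window < 1)
    stop("envelope_window must be >= 1", call. = FALSE)
  class(cfg) <- "bemd_config"
  cfg
}

#' Bi-dimensional empirical mode decomposition
#'
#' Splits an image into `n` IMF images at increasing spatial scale plus a
#' slowly varying residual, so that `sum(IMFs) + residual` reproduces the
#' input exactly (an identity of the sifting construction). Envelopes are
#' estimated by the fast order-statistics scheme: morphological closing
#' (moving max then min) and opening (moving min then max) over a box
#' window, with reflective border padding; the closing/opening pair
#' brackets oscillations at the window scale while following sharp object
#' boundaries exactly, which keeps the fruit silhouette in the residual.
#' The window doubles per successive IMF. Sifting on each mode repeats
#' until the envelope-mean energy is negligible or the iteration cap is
#' hit.
#'
#' If an intermediate remainder runs out of local extrema before `n` modes
#' have been extracted, the remaining IMFs are returned as zero images with
#' a warning; the decomposition identity still holds.
#'
#' @param image Numeric matrix, finite and non-negative.
#' @param config A [bemd_config()].
#' @return An object of class `cfi_bemd`: list with `imfs` (list of `n`
#'   matrices, finest first), `residual`, `source` and `config`.
#' @export
bemd_decompose <- function(image, config = bemd_config()) {
  .check_image(image)
  if (any(image < 0)) stop("image must be non-negative", call. = FALSE)
  if (min(dim(image)) <= 4 * config$envelope_window)
    stop("image too small: each side must exceed 4 * envelope_window",
         call. = FALSE)
  n <- config$n
  # largest window kept well below the object scale so the silhouette and
  # its interior trend stay in the residual
  wcap <- max(1L, floor(min(dim(image)) / 16))
  x <- image
  imfs <- vector("list", n)
  for (i in seq_len(n)) {
    w <- min(config$envelope_window * 2^(i - 1), wcap)
    ext <- .count_extrema(x)
    if (min(ext) < 4) {
      warning("too few extrema after ", i - 1,
              " IMFs; remaining modes returned as zero images")
      for (j in i:n) imfs[[j]] <- matrix(0, nrow(image), ncol(image))
      break
    }
    h <- x
    for (iter in seq_len(config$max_sift_iterations)) {
      # morphological closing/opening: envelopes bracket oscillations at
      # scale <= w yet follow step edges without spatial spread, so sharp
      # object boundaries stay in the residual rather than leaking into
      # the modes
      upper <- .box_extremum(.box_extremum(h, w, "max", "disc"),
                             w, "min", "disc")
      lower <- .box_extremum(.box_extremum(h, w, "min", "disc"),
                             w, "max", "disc")
      em <- (upper + lower) / 2
      h <- h - em
      if (sum(em^2) <= config$sift_tolerance * max(sum(h^2), 1e-300)) break
    }
    imfs[[i]] <- h
    x <- x - h
  }
  structure(list(imfs = imfs, residual = x, source = image,
                 config = config),
            class = "cfi_bemd")
}

#' @export
print.cfi_bemd <- function(x, ...) {
  cat("<cfi_bemd> ", length(x$imfs), " IMFs + residual for a ",
      nrow(x$source), "x", ncol(x$source), " image (k = ", x$config$k,
      ")\n", sep = "")
  invisible(x)
}

#' Vignetting correction by IMF reconstruction
#'
#' Computes the ratio image
#' `(FI + IMF_2 + ... + IMF_k - IMF_1) / max(R, floor)` element-wise: the
#' residual `R` carries the slowly varying vignetting trend, the first IMF
#' is excluded to suppress high-frequency noise, and the division yields a
#' dimensionless image that is markedly more uniform over the fruit than
#' the raw input. The guard floor is `residual_floor * max(FI)`, which
#' protects the near-zero background without touching the fruit region.
#'
#' @param result A `cfi_bemd` decomposition.
#' @param config Optional [bemd_config()] overriding the one stored in
#'   `result` (e.g. to vary `k` without re-decomposing); `k` must be
#'   smaller than the number of extracted IMFs.
#' @return The corrected image (numeric matrix, dimensionless).
#' @export
correct_vignetting <- function(result, config = result$config) {
  stopifnot(inherits(result, "cfi_bemd"))
  k <- config$k
  if (k < 1 || k >= length(result$imfs))
    stop("reconstruction index must satisfy 1 <= k < n", call. = FALSE)
  num <- result$source - result$imfs[[1]]
  if (k >= 2)
    for (i in 2:k) num <- num + result$imfs[[i]]
  floor_val <- config$residual_floor * max(result$source)
  num / pmax(result$residual, floor_val)
}
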