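#' Intensity histogram of an image
#'
#' Equal-width binning over `[0, max(image)]`, the form consumed by
#' [unimodal_threshold()].
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param bins Number of equal-width bins.
#' @return List with `counts`, `mids` and `breaks`.
#' @export
image_histogram <- function(image, bins = 256) {
  .check_image(image)
  if (any(image < 0)) stop("intensities must be non-negative", call. = FALSE)
  top <- max(image)
  if (top <= 0) stop("image is identically zero", call. = FALSE)
  breaks <- seq(0, top, length.out = bins + 1)
  idx <- findInterval(image, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  list(counts = tabulate(idx, nbins = bins),
       mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
       breaks = breaks)
}

#' Rosin threshold for a unimodal histogram
#'
#' Finds the corner of a unimodal histogram whose single main peak sits at
#' the low-intensity end (the background of a fluorescence image): the
#' threshold is the upper edge of the bin maximising the perpendicular
#' distance to the straight line drawn from the histogram peak to the
#' last non-empty bin (the corner bin's own contents stay with the
#' background).
#' A light 3-bin moving average stabilises the peak location under noise;
#' the distances themselves are computed on the raw histogram. Ties go to
#' the lowest intensity (the more inclusive mask).
#'
#' @param counts Bin counts, or a list with `counts` and `mids` as returned
#'   by [image_histogram()].
#' @param mids Bin centre intensities (ignored when `counts` is a list).
#' @return The threshold intensity (scalar), strictly above the mode.
#' @export
unimodal_threshold <- function(counts, mids = NULL) {
  if (is.list(counts)) { mids <- counts$mids; counts <- counts$counts }
  if (is.null(mids)) mids <- seq_along(counts)
  stopifnot(length(counts) == length(mids))
  nonempty <- which(counts > 0)
  if (length(nonempty) < 2)
    stop("degenerate histogram: fewer than 2 non-empty bins", call. = FALSE)
  if (length(unique(counts[seq(min(nonempty), max(nonempty))])) == 1)
    stop("flat histogram: no unimodal structure", call. = FALSE)
  nb <- length(counts)
  sm <- (c(counts[1], counts[-nb]) + counts + c(counts[-1], counts[nb])) / 3
  peak <- which.max(sm)
  last <- max(nonempty)
  if (peak >= last)
    stop("histogram mode coincides with the last non-empty bin; ",
         "no low-intensity background peak", call. = FALSE)
  cand <- seq(peak + 1, last)
  dx <- mids[last] - mids[peak]
  dy <- counts[last] - counts[peak]
  d <- abs(dx * (counts[cand] - counts[peak]) -
             (mids[cand] - mids[peak]) * dy) / sqrt(dx^2 + dy^2)
  # upper edge of the corner bin: its own contents belong to the
  # background side of the cut
  mids[cand[which.max(d)]] + (mids[2] - mids[1]) / 2
}

#' Segment the fruit from the background
#'
#' Thresholds the 750 nm band with [unimodal_threshold()], keeps the
#' largest 8-connected foreground component and fills interior holes so
#' that dark lesions remain part of the fruit mask. The same mask is meant
#' to be reused unchanged for the 675 nm image of the sample.
#'
#' @param image_750 Numeric matrix: the 750 nm band.
#' @param bins Histogram bins passed to [image_histogram()].
#' @return An object of class `cfi_mask`: list with `mask` (logical
#'   matrix), `threshold` and `histogram` (the raw histogram used).
#' @export
segment_fruit <- function(image_750, bins = 256) {
  h <- image_histogram(image_750, bins = bins)
  thr <- unimodal_threshold(h)
  fg <- image_750 > thr
  if (!any(fg))
    stop("empty foreground after thresholding at ", signif(thr, 6),
         call. = FALSE)
  lab <- .label8(fg)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  mask <- matrix(filled > 0.5, nrow(image_750), ncol(image_750))
  structure(list(mask = mask, threshold = thr, histogram = h),
            class = "cfi_mask")
}

#' @export
print.cfi_mask <- function(x, ...) {
  cat("<cfi_mask> ", sum(x$mask), " px fruit region, threshold ",
      signif(x$threshold, 6), " counts\n", sep = "")
  invisible(x)
}
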