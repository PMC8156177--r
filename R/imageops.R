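# Low-level raster helpers shared by the generator, segmentation and BEMD.
# All operators work on plain numeric matrices; EBImage provides the fast
# morphology and Gaussian filtering kernels underneath.

# symmetric (edge-inclusive) reflective padding by p pixels on every side
.pad_reflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  p <- min(p, nr - 1, nc - 1)
  ri <- c(seq(p, 1), seq_len(nr), seq(nr, nr - p + 1))
  ci <- c(seq(p, 1), seq_len(nc), seq(nc, nc - p + 1))
  list(m = m[ri, ci, drop = FALSE], p = p)
}

.crop <- function(m, p, nr, nc) m[p + seq_len(nr), p + seq_len(nc), drop = FALSE]

# Gaussian blur with reflective boundary handling
.gblur_padded <- function(m, sigma) {
  if (sigma <= 0) return(m)
  pad <- .pad_reflect(m, ceiling(3 * sigma) + 1)
  sm <- as.matrix(EBImage::gblur(pad$m, sigma = sigma))
  .crop(sm, pad$p, nrow(m), ncol(m))
}

# moving max/min over a (2w+1)^2 box window, reflective boundary.
# EBImage grayscale morphology assumes intensities in [0,1], so the input
# is affinely mapped there and back (rank filters commute with positive
# affine maps).
.box_extremum <- function(m, w, what = c("max", "min"), shape = "box") {
  what <- match.arg(what)
  mn <- min(m); mx <- max(m)
  if (mx == mn) return(m)
  pad <- .pad_reflect((m - mn) / (mx - mn), w)
  brush <- EBImage::makeBrush(2 * min(w, pad$p) + 1, shape = shape)
  out <- if (what == "max") EBImage::dilate(pad$m, brush)
         else EBImage::erode(pad$m, brush)
  .crop(as.matrix(out), pad$p, nrow(m), ncol(m)) * (mx - mn) + mn
}

# strict 8-neighbour local extrema counts (plateaus are not extrema)
.count_extrema <- function(m) {
  mx <- .box_extremum(m, 1, "max")
  mn <- .box_extremum(m, 1, "min")
  c(maxima = sum(m == mx & m > mn), minima = sum(m == mn & m < mx))
}
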