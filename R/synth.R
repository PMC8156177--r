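#' Scene parameters for synthetic dual-band fluorescence images
#'
#' Builds the parameter set from which synthetic chlorophyll-fluorescence
#' image pairs of single cucumber fruit are rendered. Geometric defaults
#' (fruit axes, lesion radii) are expressed at a 512x512 reference frame and
#' scale linearly with `image_size`, so the same physical scene can be
#' rendered at different resolutions.
#'
#' The scene model is: an elongated superellipse fruit of constant emission
#' at 750 nm on a near-zero background, darkened soft-edged lesion blobs
#' whose number and size grow with injury class, a multiplicative cos^4
#' radial vignetting field normalised to 1 at the image centre, a 675 nm
#' band equal to the noise-free 750 nm structure scaled by
#' `band_ratio_675`, and additive Gaussian noise clipped at zero.
#'
#' @param image_size Side length in pixels of the square frame.
#' @param fruit_axes Semi-major/semi-minor axes of the fruit in pixels
#'   (axis ratio must be >= 2).
#' @param fruit_emission_750 Mean fruit-region intensity at 750 nm, in
#'   detector counts.
#' @param band_ratio_675 Multiplicative factor in (0,1) mapping 750 nm fruit
#'   intensity to the dimmer 675 nm band.
#' @param background_level Mean background counts (near zero emission).
#' @param vignetting_strength Fractional intensity falloff at the image
#'   corner relative to the centre, in [0,1).
#' @param lesion_count_range Named list with integer ranges `c0`, `c1`, `c2`
#'   of lesion counts per injury class.
#' @param lesion_radius_range Named list with radius ranges (pixels) `c1`,
#'   `c2`; class-1 radii must lie strictly below the class-2 minimum.
#' @param lesion_darkening Fractional intensity reduction at a lesion centre,
#'   in [0,1).
#' @param noise_sd Additive Gaussian noise standard deviation in counts.
#' @param fruit_exponent Superellipse exponent (2 = ellipse; >2 boxier).
#' @param seed RNG seed used by [generate_sample()].
#' @return An object of class `scene_params` (a validated list).
#' @seealso [generate_sample()], [generate_dataset()]
#' @export
scene_params <- function(image_size = 512,
                         fruit_axes = c(0.41, 0.155) * image_size,
                         fruit_emission_750 = 39000,
                         band_ratio_675 = 0.35,
                         background_level = 400,
                         vignetting_strength = 0.25,
                         lesion_count_range = list(c0 = c(0L, 0L),
                                                   c1 = c(1L, 3L),
                                                   c2 = c(4L, 8L)),
                         lesion_radius_range = list(
                           c1 = c(4, 9) * image_size / 512,
                           c2 = c(10.5, 24) * image_size / 512),
                         lesion_darkening = 0.5,
                         noise_sd = 250,
                         fruit_exponent = 2.5,
                         seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            fruit_axes = as.numeric(fruit_axes),
            fruit_emission_750 = fruit_emission_750,
            band_ratio_675 = band_ratio_675,
            background_level = background_level,
            vignetting_strength = vignetting_strength,
            lesion_count_range = lesion_count_range,
            lesion_radius_range = lesion_radius_range,
            lesion_darkening = lesion_darkening,
            noise_sd = noise_sd,
            fruit_exponent = fruit_exponent,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  stopifnot(inherits(p, "scene_params"))
  if (p$image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (length(p$fruit_axes) != 2 || any(p$fruit_axes <= 0))
    stop("fruit_axes must be two positive lengths", call. = FALSE)
  if (p$fruit_axes[1] / p$fruit_axes[2] < 2)
    stop("fruit must be elongated: axis ratio must be >= 2", call. = FALSE)
  if (!(p$band_ratio_675 > 0 && p$band_ratio_675 < 1))
    stop("band_ratio_675 must lie in (0, 1)", call. = FALSE)
  if (!(p$vignetting_strength >= 0 && p$vignetting_strength < 1))
    stop("vignetting_strength must lie in [0, 1)", call. = FALSE)
  if (p$background_level < 0 || p$fruit_emission_750 <= 0)
    stop("intensity levels must be non-negative", call. = FALSE)
  if (p$background_level >= p$fruit_emission_750 * (1 - p$vignetting_strength))
    stop("background_level must be below the dimmest fruit intensity ",
         "(fruit_emission_750 * (1 - vignetting_strength))", call. = FALSE)
  if (!all(c("c0", "c1", "c2") %in% names(p$lesion_count_range)))
    stop("lesion_count_range needs entries c0, c1, c2", call. = FALSE)
  if (!all(c("c1", "c2") %in% names(p$lesion_radius_range)))
    stop("lesion_radius_range needs entries c1, c2", call. = FALSE)
  r1 <- p$lesion_radius_range$c1; r2 <- p$lesion_radius_range$c2
  if (max(r1) >= min(r2))
    stop("class-1 lesion radii must lie strictly below the class-2 minimum",
         call. = FALSE)
  if (any(c(r1, r2) <= 0)) stop("lesion radii must be positive", call. = FALSE)
  if (!(p$lesion_darkening >= 0 && p$lesion_darkening < 1))
    stop("lesion_darkening must lie in [0, 1)", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(p)
}

# cos^4 vignetting field, 1 at the frame centre, (1 - strength) at corners
.vignette_field <- function(n, strength) {
  if (strength == 0) return(matrix(1, n, n))
  ctr <- (n + 1) / 2
  rmax <- sqrt(2) * (n - 1) / 2
  theta_max <- acos((1 - strength)^0.25)
  f <- rmax / tan(theta_max)
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  1 / (1 + r2 / f^2)^2
}

#' Generate one labelled synthetic dual-band sample
#'
#' Renders a single fruit scene at the given injury class and returns both
#' emission bands together with ground-truth rasters. The render is fully
#' deterministic for a fixed `params$seed`. Pixel values are kept as
#' unquantised doubles; quantisation to 16-bit integers happens only when
#' samples are written to disk by [write_dataset()].
#'
#' @param params A [scene_params()] object.
#' @param label Injury class: 0 (normal), 1 (mild, few small spots),
#'   2 (severe, more/larger patches).
#' @return An object of class `cfi_sample`: a list with `image_675`,
#'   `image_750` (numeric matrices in counts), `truth_mask` and
#'   `truth_lesions` (logical matrices), `label`, plus the noise-free
#'   renders (`noisefree_750`, `noisefree_675`), the flat scene
#'   (`scene_750`), and the applied `vignette_field`.
#' @export
generate_sample <- function(params, label) {
  validate_scene_params(params)
  if (!label %in% 0:2) stop("label must be 0, 1 or 2", call. = FALSE)
  set.seed(params$seed)
  n <- params$image_size
  a <- params$fruit_axes[1]; b <- params$fruit_axes[2]
  e <- params$fruit_exponent

  # fruit geometry: random orientation, slight centre jitter
  theta <- runif(1, 0, pi)
  ctr <- (n + 1) / 2 + runif(2, -0.02 * n, 0.02 * n)
  xs <- matrix(rep(seq_len(n), each = n), n, n) - ctr[2]  # column coord
  ys <- matrix(rep(seq_len(n), n), n, n) - ctr[1]         # row coord
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  mask <- (abs(u) / a)^e + (abs(v) / b)^e <= 1
  if (!any(mask)) stop("fruit does not intersect the frame", call. = FALSE)

  # lesions: darkened soft blobs wholly inside the fruit
  cls <- paste0("c", label)
  cnt_rng <- params$lesion_count_range[[cls]]
  n_lesions <- if (label == 0) 0L else
    sample(seq.int(cnt_rng[1], cnt_rng[2]), 1)
  lesions <- matrix(FALSE, n, n)
  atten <- matrix(1, n, n)
  if (n_lesions > 0) {
    rad_rng <- params$lesion_radius_range[[cls]]
    dmap <- EBImage::distmap(EBImage::Image(mask * 1))
    dmap <- matrix(as.numeric(dmap), n, n)
    for (l in seq_len(n_lesions)) {
      radius <- runif(1, rad_rng[1], rad_rng[2])
      candidates <- which(dmap > radius + 1)
      if (length(candidates) == 0)
        stop("lesion geometry infeasible: no placement leaves a radius-",
             round(radius, 1), " lesion wholly inside the fruit",
             call. = FALSE)
      centre <- arrayInd(candidates[sample.int(length(candidates), 1)],
                         c(n, n))
      d2 <- outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2, "+")
      disk <- d2 <= radius^2
      lesions <- lesions | disk
      blob <- .gblur_padded(disk * 1, sigma = max(radius / 3, 0.5))
      blob <- blob / max(blob)
      atten <- atten * (1 - params$lesion_darkening * blob)
    }
  }

  scene <- ifelse(mask, params$fruit_emission_750 * atten,
                  params$background_level)
  field <- .vignette_field(n, params$vignetting_strength)
  nf750 <- scene * field
  nf675 <- nf750 * params$band_ratio_675
  clip16 <- function(x) pmin(pmax(x, 0), 65535)
  img750 <- if (params$noise_sd > 0)
    clip16(nf750 + rnorm(n * n, 0, params$noise_sd)) else nf750
  img675 <- if (params$noise_sd > 0)
    clip16(nf675 + rnorm(n * n, 0, params$noise_sd)) else nf675
  dim(img750) <- dim(img675) <- c(n, n)

  structure(list(image_675 = img675, image_750 = img750,
                 truth_mask = mask, truth_lesions = lesions,
                 label = as.integer(label),
                 noisefree_750 = nf750, noisefree_675 = nf675,
                 scene_750 = scene, vignette_field = field,
                 seed = params$seed, params = params),
            class = "cfi_sample")
}

#' @export
print.cfi_sample <- function(x, ...) {
  cat("<cfi_sample> ", nrow(x$image_750), "x", ncol(x$image_750),
      " dual-band pair, injury class ", x$label,
      ", ", sum(x$truth_lesions), " lesion px (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' Draws per-sample seeds from one master seed, then renders each sample
#' with [generate_sample()]; the result is reproducible bit-for-bit for a
#' fixed seed and is ordered by class (all class-0 samples first).
#'
#' @param params A [scene_params()] object shared by all samples.
#' @param counts Integer vector of length 3: samples per class 0, 1, 2.
#' @param seed Master seed; defaults to `params$seed`.
#' @return An object of class `cfi_dataset`: list with `samples` (list of
#'   `cfi_sample`) and `manifest` (data frame of sample_id, label, seed).
#' @export
generate_dataset <- function(params, counts, seed = params$seed) {
  validate_scene_params(params)
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 0))
    stop("counts must be three non-negative integers", call. = FALSE)
  total <- sum(counts)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, total)
  labels <- rep(0:2, counts)
  samples <- vector("list", total)
  for (i in seq_len(total)) {
    pi <- params
    pi$seed <- seeds[i]
    samples[[i]] <- generate_sample(pi, labels[i])
  }
  ids <- sprintf("s%04d", seq_len(total))
  structure(list(samples = setNames(samples, ids),
                 manifest = data.frame(sample_id = ids, label = labels,
                                       seed = seeds,
                                       stringsAsFactors = FALSE),
                 seed = as.integer(seed)),
            class = "cfi_dataset")
}

#' @export
print.cfi_dataset <- function(x, ...) {
  tab <- table(factor(x$manifest$label, levels = 0:2))
  cat("<cfi_dataset> ", length(x$samples), " dual-band samples (class 0/1/2: ",
      paste(tab, collapse = "/"), "), master seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a dataset as 16-bit TIFF pairs with a CSV manifest
#'
#' Images are quantised to 16-bit unsigned integers. Filenames encode the
#' sample id, band and label (`<id>_<band>_class<label>.tif`); a
#' `manifest.csv` records ids, labels, seeds and file paths.
#'
#' @param dataset A `cfi_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame with path columns added.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cfi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$path_675 <- file.path(dir, sprintf("%s_675_class%d.tif",
                                         man$sample_id, man$label))
  man$path_750 <- file.path(dir, sprintf("%s_750_class%d.tif",
                                         man$sample_id, man$label))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    tiff::writeTIFF(round(s$image_675) / 65535, man$path_675[i],
                    bits.per.sample = 16)
    tiff::writeTIFF(round(s$image_750) / 65535, man$path_750[i],
                    bits.per.sample = 16)
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the TIFF pairs.
#' @return A `cfi_dataset` whose samples hold the two image bands and the
#'   label; ground-truth rasters are not stored on disk and are `NULL`.
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  samples <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    i675 <- tiff::readTIFF(man$path_675[i]) * 65535
    i750 <- tiff::readTIFF(man$path_750[i]) * 65535
    samples[[i]] <- structure(
      list(image_675 = i675, image_750 = i750,
           truth_mask = NULL, truth_lesions = NULL,
           label = man$label[i], seed = man$seed[i]),
      class = "cfi_sample")
  }
  structure(list(samples = setNames(samples, man$sample_id),
                 manifest = man, seed = NA_integer_),
            class = "cfi_dataset")
}
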