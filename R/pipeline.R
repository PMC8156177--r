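#' Run the image pipeline over a dataset and build the feature table
#'
#' For each sample: segment the fruit on the 750 nm band
#' ([segment_fruit()]), decompose both bands with [bemd_decompose()],
#' apply the vignetting correction ([correct_vignetting()]), extract the
#' 167 per-band features from the corrected images under the shared fruit
#' mask, and fuse them to 334 features.
#'
#' @param dataset A `cfi_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @param config A [bemd_config()] used for both bands.
#' @param bins Histogram bins for segmentation.
#' @return An object of class `cfi_features`: list with `features`
#'   (numeric matrix, samples x 334 fused features), `labels` (integer
#'   injury classes), `thresholds` (per-sample segmentation thresholds)
#'   and `band = "fused"`.
#' @export
extract_dataset_features <- function(dataset, config = bemd_config(),
                                     bins = 256) {
  stopifnot(inherits(dataset, "cfi_dataset"))
  n <- length(dataset$samples)
  feats <- NULL
  thresholds <- numeric(n)
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    seg <- segment_fruit(s$image_750, bins = bins)
    thresholds[i] <- seg$threshold
    c675 <- correct_vignetting(bemd_decompose(s$image_675, config), config)
    c750 <- correct_vignetting(bemd_decompose(s$image_750, config), config)
    v <- fuse_features(extract_features(c675, seg$mask, "675"),
                       extract_features(c750, seg$mask, "750"))
    if (is.null(feats))
      feats <- matrix(NA_real_, n, length(v),
                      dimnames = list(names(dataset$samples), names(v)))
    feats[i, ] <- v
  }
  structure(list(features = feats,
                 labels = dataset$manifest$label,
                 thresholds = thresholds, band = "fused"),
            class = "cfi_features")
}

#' @export
print.cfi_features <- function(x, ...) {
  cat("<cfi_features> ", nrow(x$features), " samples x ", ncol(x$features),
      " features (", x$band, " input)\n", sep = "")
  invisible(x)
}

#' Restrict a fused feature table to one band
#'
#' @param features A `cfi_features` table with fused (334) columns.
#' @param band `"675"`, `"750"` or `"fused"` (identity).
#' @return A `cfi_features` with the selected columns.
#' @export
select_band <- function(features, band = c("fused", "675", "750")) {
  band <- match.arg(band)
  stopifnot(inherits(features, "cfi_features"))
  if (band == "fused") return(features)
  keep <- endsWith(colnames(features$features), paste0("_", band))
  out <- features
  out$features <- features$features[, keep, drop = FALSE]
  out$band <- band
  out
}

#' Feature-wise standardisation with training statistics
#'
#' Fits per-feature mean and standard deviation on the training rows only
#' and transforms every row with those statistics, so training columns
#' have exactly zero mean and unit variance while test rows see no
#' leakage. A zero-variance training feature is mapped to 0 with a
#' warning.
#'
#' @param features A `cfi_features` table or a numeric matrix.
#' @param train_ids Row indices or row names of the training samples.
#' @return The input with standardised `features` and an attached `norm`
#'   element (list with `center`, `scale`, `train_ids`).
#' @export
normalize_features <- function(features, train_ids) {
  x <- if (inherits(features, "cfi_features")) features$features else features
  if (is.character(train_ids)) train_ids <- match(train_ids, rownames(x))
  if (length(train_ids) < 2)
    stop("need at least 2 training rows", call. = FALSE)
  std <- .standardize(x[train_ids, , drop = FALSE], x)
  if (any(std$scale == 0))
    warning(sum(std$scale == 0),
            " zero-variance training feature(s) standardised to 0")
  if (inherits(features, "cfi_features")) {
    features$features <- std$all
    features$norm <- list(center = std$center, scale = std$scale,
                          train_ids = train_ids)
    features
  } else std$all
}

# centre/scale `all` using statistics fitted on `train`; sd uses the n-1
# divisor so training columns get unit sample variance
.standardize <- function(train, all) {
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  sc <- ifelse(scale == 0, 1, scale)
  out <- sweep(sweep(all, 2, center), 2, sc, "/")
  out[, scale == 0] <- 0
  list(all = out, center = center, scale = scale)
}
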