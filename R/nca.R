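# Neighborhood component analysis feature ranking: learn non-negative
# per-feature distance weights that maximise the expected leave-one-out
# soft nearest-neighbour accuracy with an L2 shrinkage penalty on the
# weights. Distances are weighted L1: d(x_i, x_j) = sum_r w_r^2 |x_ir - x_jr|.

# pairwise |x_ir - x_jr| flattened to an (n*n) x p matrix, pair (i,j)
# stored at row (i-1)*n + j
.nca_pairdiff <- function(x) {
  n <- nrow(x); p <- ncol(x)
  D <- matrix(0, n * n, p)
  for (r in seq_len(p)) D[, r] <- abs(rep(x[, r], each = n) - x[, r])
  D
}

# objective and gradient of the regularised NCA criterion at weights w
.nca_objective <- function(w, D, same, lambda) {
  n <- nrow(same)
  d <- matrix(D %*% (w^2), n, n)        # d[j, i] = dist(i, j)
  d <- t(d)
  diag(d) <- Inf
  dmin <- apply(d, 1, min)
  dmin[!is.finite(dmin)] <- 0
  K <- exp(-(d - dmin))                  # row-stabilised soft neighbours
  diag(K) <- 0
  denom <- pmax(rowSums(K), 1e-300)
  P <- K / denom
  p_i <- rowSums(P * same)
  value <- sum(p_i) - lambda * sum(w^2)
  C <- p_i * P - same * P                # C[i, j]
  cvec <- as.vector(t(C))                # pair (i,j) at (i-1)*n + j
  grad <- 2 * w * as.numeric(crossprod(D, cvec)) - 2 * lambda * w
  list(value = value, gradient = grad, p = p_i)
}

#' NCA feature ranking
#'
#' Learns one importance weight per feature by gradient-based (BFGS)
#' maximisation of the regularised soft leave-one-out nearest-neighbour
#' accuracy, starting from uniform weights. Reported importances are the
#' squared weights normalised to a maximum of 1; features are ranked by
#' descending importance.
#'
#' @param x Numeric feature matrix (rows = samples, already normalised).
#' @param y Class labels.
#' @param lambda Non-negative shrinkage strength; defaults to
#'   `1 / nrow(x)`.
#' @param max_iter BFGS iteration cap.
#' @return An object of class `cfi_nca`: `weights` (importances in
#'   `[0, 1]`), `ranking` (feature indices by descending importance),
#'   `raw_weights`, `lambda` and the attained `objective`.
#' @export
nca_rank <- function(x, y, lambda = 1 / nrow(x), max_iter = 200L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  D <- .nca_pairdiff(x)
  same <- outer(y, y, "==") * 1
  diag(same) <- 0
  fn <- function(w) {
    o <- .nca_objective(w, D, same, lambda)
    if (!all(is.finite(o$gradient)))
      stop("non-finite NCA gradient", call. = FALSE)
    -o$value
  }
  gr <- function(w) -.nca_objective(w, D, same, lambda)$gradient
  opt <- optim(rep(1, ncol(x)), fn, gr, method = "BFGS",
               control = list(maxit = max_iter))
  imp <- opt$par^2
  top <- max(imp)
  weights <- if (top > 0) imp / top else imp
  structure(list(weights = weights,
                 ranking = order(weights, decreasing = TRUE),
                 raw_weights = opt$par, lambda = lambda,
                 objective = -opt$value),
            class = "cfi_nca")
}

#' @export
print.cfi_nca <- function(x, ...) {
  cat("<cfi_nca> ", length(x$weights), " feature weights (lambda = ",
      format(x$lambda, digits = 4), "); top feature index ",
      x$ranking[1], "\n", sep = "")
  invisible(x)
}

#' @export
plot.cfi_nca <- function(x, ...) {
  plot(x$weights, type = "h", xlab = "feature index",
       ylab = "normalized weight", ...)
  invisible(x)
}

#' Incremental evaluation of the top-ranked features
#'
#' For each replicate: draw the stratified split, standardise on the
#' training rows, rank features by NCA fitted on the training rows only
#' (no leakage), then for every subset size m = 1..`top` train a
#' cross-validated linear SVM on the top-m features and record the test
#' accuracy; the full-feature accuracy of the same replicate is the
#' reference. The selected size is the smallest m whose mean accuracy
#' reaches the full-feature mean accuracy minus one standard error.
#'
#' @param features A `cfi_features` table.
#' @param config A [train_config()].
#' @param top Number of top-ranked features to scan (truncated with a
#'   warning when fewer features exist).
#' @param lambda NCA shrinkage; default `1 / n_train`.
#' @return An object of class `cfi_selection`: `curve` (data frame of
#'   m, mean and SE of test accuracy in percent), `selected_size`,
#'   `full_mean`, `full_se`, and the per-replicate accuracy matrix.
#' @export
incremental_selection <- function(features, config = train_config(),
                                  top = 100L, lambda = NULL) {
  x <- features$features
  y <- .task_labels(features$labels, config$task)
  p <- ncol(x)
  if (p < top) {
    warning("only ", p, " features available; curve truncated")
    top <- p
  }
  acc <- matrix(NA_real_, config$replicates, top)
  full <- numeric(config$replicates)
  for (r in seq_len(config$replicates)) {
    seed_r <- config$seed + r
    sp <- split_data(y, config$split_ratio, seed = seed_r,
                     min_train = config$cv_folds)
    std <- .standardize(x[sp$train, , drop = FALSE], x)
    xtr <- std$all[sp$train, , drop = FALSE]
    xte <- std$all[sp$test, , drop = FALSE]
    lam <- if (is.null(lambda)) 1 / length(sp$train) else lambda
    rk <- nca_rank(xtr, y[sp$train], lambda = lam)$ranking
    full_fit <- train_svm(xtr, y[sp$train], config, fold_seed = seed_r)
    full[r] <- 100 * mean(.predict_ovr(full_fit, xte) == y[sp$test])
    for (m in seq_len(top)) {
      cols <- rk[seq_len(m)]
      fit <- train_svm(xtr[, cols, drop = FALSE], y[sp$train], config,
                       fold_seed = seed_r)
      acc[r, m] <- 100 * mean(.predict_ovr(fit, xte[, cols, drop = FALSE])
                              == y[sp$test])
    }
  }
  mean_acc <- colMeans(acc)
  se_acc <- apply(acc, 2, sd) / sqrt(nrow(acc))
  full_mean <- mean(full)
  full_se <- sd(full) / sqrt(length(full))
  hit <- which(mean_acc >= full_mean - full_se)
  structure(list(curve = data.frame(m = seq_len(top), mean_acc = mean_acc,
                                    se_acc = se_acc),
                 selected_size = if (length(hit)) min(hit)
                                 else which.max(mean_acc),
                 full_mean = full_mean, full_se = full_se,
                 per_replicate = acc, task = config$task),
            class = "cfi_selection")
}

#' @export
print.cfi_selection <- function(x, ...) {
  cat("<cfi_selection> top-", nrow(x$curve), " incremental curve (",
      x$task, "-class); selected size ", x$selected_size,
      " (full-feature ACC ", sprintf("%.1f", x$full_mean), " +/- ",
      sprintf("%.1f", x$full_se), " %)\n", sep = "")
  invisible(x)
}

#' @export
plot.cfi_selection <- function(x, ...) {
  plot(x$curve$m, x$curve$mean_acc, type = "l",
       xlab = "number of top-ranked features", ylab = "mean ACC (%)", ...)
  abline(h = x$full_mean, lty = 2)
  abline(v = x$selected_size, lty = 3)
  invisible(x)
}
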