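#' Training configuration for replicated SVM evaluation
#'
#' @param task `"two"` (normal vs injured, classes 1 and 2 merged) or
#'   `"three"` (normal / mildly injured / severely injured).
#' @param split_ratio Training fraction of the random stratified split.
#' @param cv_folds Folds for the cross-validated regularisation search.
#' @param c_grid Candidate values of the soft-margin cost parameter; must
#'   lie within `[1e-4, 1e4]`. The default samples that range at
#'   half-decade steps (17 points).
#' @param replicates Number of random split replicates.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("two", "three"), split_ratio = 0.6,
                         cv_folds = 5L, c_grid = 10^seq(-4, 4, by = 0.5),
                         replicates = 30L, seed = 1L) {
  task <- match.arg(task)
  if (!(split_ratio > 0 && split_ratio < 1))
    stop("split_ratio must lie in (0, 1)", call. = FALSE)
  if (any(c_grid < 1e-4 * (1 - 1e-8)) || any(c_grid > 1e4 * (1 + 1e-8)))
    stop("c_grid must lie within [1e-4, 1e4]", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(task = task, split_ratio = split_ratio,
                 cv_folds = as.integer(cv_folds),
                 c_grid = sort(as.numeric(c_grid)),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "train_config")
}

# injury classes -> task-level factor
.task_labels <- function(labels, task) {
  if (is.factor(labels)) return(labels)
  if (task == "two")
    factor(ifelse(labels == 0, "normal", "injured"),
           levels = c("normal", "injured"))
  else
    factor(paste0("class", labels),
           levels = c("class0", "class1", "class2"))
}

#' Stratified random train/test split
#'
#' Splits by class with largest-remainder rounding, so the total training
#' size equals `round(split_ratio * n)` and per-class proportions match
#' the overall proportions to within one sample.
#'
#' @param labels Class labels (vector or factor).
#' @param split_ratio Training fraction.
#' @param seed RNG seed; the split is reproducible from it.
#' @param min_train Minimum training members required per class
#'   (typically the number of CV folds).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_data <- function(labels, split_ratio = 0.6, seed = 1L,
                       min_train = 5L) {
  labels <- as.factor(labels)
  n <- length(labels)
  classes <- levels(labels)
  ncls <- table(labels)
  target <- round(split_ratio * n)
  exact <- split_ratio * as.numeric(ncls)
  base <- floor(exact)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  set.seed(seed)
  train <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    ntr <- base[ci]
    if (ntr < min_train || ntr >= length(idx))
      stop("class '", classes[ci], "' too small for a ", split_ratio,
           " split with at least ", min_train, " training members",
           call. = FALSE)
    train <- c(train, sort(sample(idx, ntr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

# --- linear soft-margin SVM (e1071/libsvm backend) --------------------

# fit one binary linear SVM and return it with its positive level recorded
.svm_binary <- function(x, y, cost) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    type = "C-classification")
  fit
}

# decision values oriented so positive favours `positive`
.svm_decision <- function(fit, newx, positive) {
  pr <- predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  if (lab[1] == positive) as.numeric(dv) else -as.numeric(dv)
}

#' Train a linear soft-margin SVM with cross-validated cost
#'
#' For every candidate cost the stratified `cv_folds`-fold
#' cross-validation accuracy on the training rows is computed; the best
#' cost (ties resolved towards the smaller cost, i.e. the wider margin)
#' is refit on the full training set. With more than two classes a
#' one-vs-rest ensemble is fit and prediction takes the class with the
#' largest oriented decision value.
#'
#' @param x Numeric feature matrix (already normalised).
#' @param y Class labels (factor or coercible).
#' @param config A [train_config()]; supplies `c_grid` and `cv_folds`.
#' @param fold_seed Seed for the CV fold assignment.
#' @return An object of class `cfi_svm` with elements `fits`, `classes`,
#'   `cost`, `cv` (data frame of cost vs CV accuracy) and `binary`.
#' @export
train_svm <- function(x, y, config = train_config(), fold_seed = config$seed) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("training data contain a single class", call. = FALSE)
  folds <- .make_folds(y, config$cv_folds, fold_seed)
  cv_acc <- vapply(config$c_grid, function(cost) {
    accs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      fit <- .fit_ovr(x[tr, , drop = FALSE], y[tr], cost)
      mean(.predict_ovr(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(cv_acc)          # first max: smallest cost wins ties
  fit <- .fit_ovr(x, y, config$c_grid[best])
  structure(c(fit, list(cost = config$c_grid[best],
                        cv = data.frame(cost = config$c_grid,
                                        accuracy = cv_acc))),
            class = "cfi_svm")
}

.make_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_ovr <- function(x, y, cost) {
  y <- droplevels(y)
  classes <- levels(y)
  if (length(classes) == 2) {
    list(fits = list(.svm_binary(x, y, cost)), classes = classes,
         binary = TRUE)
  } else {
    fits <- lapply(classes, function(cl) {
      yb <- factor(ifelse(y == cl, "pos", "rest"),
                   levels = c("pos", "rest"))
      .svm_binary(x, yb, cost)
    })
    list(fits = setNames(fits, classes), classes = classes, binary = FALSE)
  }
}

.predict_ovr <- function(fit, newx) {
  if (fit$binary) {
    factor(as.character(predict(fit$fits[[1]], newx)),
           levels = fit$classes)
  } else {
    dv <- vapply(fit$classes, function(cl)
      .svm_decision(fit$fits[[cl]], newx, "pos"),
      numeric(nrow(newx)))
    if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1)
    factor(fit$classes[max.col(dv, ties.method = "first")],
           levels = fit$classes)
  }
}

#' @export
predict.cfi_svm <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (type == "class") return(.predict_ovr(object, newdata))
  if (object$binary) {
    matrix(.svm_decision(object$fits[[1]], newdata, object$classes[1]),
           dimnames = list(NULL, object$classes[1]))
  } else {
    vapply(object$classes, function(cl)
      .svm_decision(object$fits[[cl]], newdata, "pos"),
      numeric(nrow(newdata)))
  }
}

#' @export
coef.cfi_svm <- function(object, ...) {
  out <- lapply(object$fits, function(fit) {
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    lev <- fit$levels[fit$labels[1]]       # class the sign favours
    flip <- if (object$binary) lev != object$classes[1] else lev != "pos"
    if (flip) { w <- -w; b <- -b }
    c(w, bias = b)
  })
  do.call(cbind, out)
}

#' @export
print.cfi_svm <- function(x, ...) {
  cat("<cfi_svm> linear soft-margin SVM (", length(x$classes),
      " classes: ", paste(x$classes, collapse = ", "),
      "), cost C = ", format(x$cost), " chosen by ",
      nrow(x$cv), "-point CV grid\n", sep = "")
  invisible(x)
}

#' Replicated split/train/test evaluation
#'
#' The central evaluation loop: for each replicate a stratified 6:4 (by
#' default) split is drawn, features are standardised on the training
#' rows, a linear SVM is trained with the cross-validated cost, and the
#' test confusion rates are recorded. All randomness derives from the
#' master seed in `config`, so results are reproducible bit-for-bit.
#'
#' @param features A `cfi_features` table (or list with `features` matrix
#'   and `labels`).
#' @param config A [train_config()].
#' @param input Optional label naming the input type (e.g. `"FI675"`,
#'   `"FI750"`, `"FI675-FI750"`); defaults to the table's band.
#' @return An object of class `cfi_replicates`: per-replicate rates (as
#'   percentages), their means and standard errors, chosen costs, and the
#'   stored confusion matrices.
#' @export
run_replicates <- function(features, config = train_config(),
                           input = NULL) {
  x <- features$features
  y <- .task_labels(features$labels, config$task)
  if (is.null(input))
    input <- switch(features$band %||% "fused",
                    "675" = "FI675", "750" = "FI750", "FI675-FI750")
  recs <- vector("list", config$replicates)
  conf <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    seed_r <- config$seed + r
    sp <- split_data(y, config$split_ratio, seed = seed_r,
                     min_train = config$cv_folds)
    std <- .standardize(x[sp$train, , drop = FALSE], x)
    fit <- train_svm(std$all[sp$train, , drop = FALSE], y[sp$train],
                     config, fold_seed = seed_r)
    pred <- .predict_ovr(fit, std$all[sp$test, , drop = FALSE])
    cr <- confusion_rates(y[sp$test], pred, config$task)
    recs[[r]] <- c(replicate = r, cr, cost = fit$cost)
    conf[[r]] <- table(truth = y[sp$test], predicted = pred)
  }
  per <- as.data.frame(do.call(rbind, recs))
  rates <- setdiff(names(per), c("replicate", "cost"))
  structure(list(per_replicate = per,
                 means = colMeans(per[rates], na.rm = TRUE),
                 se = vapply(per[rates], function(v)
                   sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), numeric(1)),
                 confusions = conf, task = config$task, input = input,
                 config = config),
            class = "cfi_replicates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cfi_replicates <- function(x, ...) {
  cat("<cfi_replicates> ", x$input, ", ", x$task, "-class task, ",
      nrow(x$per_replicate), " replicates\n", sep = "")
  m <- sprintf("%.1f", x$means)
  s <- sprintf("%.1f", x$se)
  cat(paste0("  ", names(x$means), ": ", m, " +/- ", s, " %",
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.cfi_replicates <- function(object, ...) {
  data.frame(input = object$input, task = object$task,
             metric = names(object$means),
             mean = as.numeric(object$means),
             se = as.numeric(object$se), row.names = NULL)
}

#' @export
plot.cfi_replicates <- function(x, ...) {
  m <- x$means; s <- x$se
  bp <- barplot(m, ylim = c(0, 105), ylab = "rate (%)",
                main = paste0(x$input, " (", x$task, "-class)"), ...)
  arrows(bp, m - s, bp, m + s, angle = 90, code = 3, length = 0.05)
  invisible(x)
}
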