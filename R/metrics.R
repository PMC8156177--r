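#' Per-class correct-classification rates and overall accuracy
#'
#' All rates are percentages of the associated class (or, for ACC, of all
#' tested samples). Two-class task: `TN` is the correctly classified
#' fraction of the normal class, `TP` of the injured class. Three-class
#' task: `TN` (normal), `TP1` (mildly injured) and `TP2` (severely
#' injured). A class absent from the truth yields `NA` for its rate while
#' ACC is still computed.
#'
#' @param truth,pred Equal-length label vectors: injury classes (0/1/2 or
#'   0/1 for the two-class task) or the corresponding task factors.
#' @param task `"two"` or `"three"`.
#' @return Named numeric vector (`TN`, `TP` or `TN`, `TP1`, `TP2`, then
#'   `ACC`), in percent.
#' @export
confusion_rates <- function(truth, pred, task = c("two", "three")) {
  task <- match.arg(task)
  truth <- .task_labels(truth, task)
  pred <- .task_labels(pred, task)
  if (length(truth) != length(pred))
    stop("truth and pred lengths differ", call. = FALSE)
  if (!identical(levels(truth), levels(pred)))
    stop("truth and pred levels differ", call. = FALSE)
  rate <- function(cl) {
    sel <- truth == cl
    if (!any(sel)) NA_real_ else 100 * mean(pred[sel] == cl)
  }
  out <- if (task == "two")
    c(TN = rate("normal"), TP = rate("injured"))
  else
    c(TN = rate("class0"), TP1 = rate("class1"), TP2 = rate("class2"))
  c(out, ACC = 100 * mean(pred == truth))
}

#' Compare replicate accuracies across input types (ANOVA + Fisher LSD)
#'
#' One-way ANOVA on the per-replicate ACC values across inputs; only when
#' the omnibus test is significant at `alpha` (the protected form of the
#' procedure) are all pairwise comparisons performed with Fisher's least
#' significant difference, using the pooled mean squared error. Groups
#' are summarised with a compact letter display: inputs sharing a letter
#' are not significantly different. Identical groups (zero between-group
#' variance) get the conventional p-value 1 and share one letter.
#'
#' @param summaries List of `cfi_replicates` objects (equal replicate
#'   counts required), or a named list of numeric ACC vectors.
#' @param alpha Significance level for both the ANOVA gate and the LSD.
#' @return An object of class `cfi_comparison`: `table` (input, mean, se,
#'   letter, ordered by descending mean), `anova` (F, p, dfs, MSE),
#'   `lsd` (the least significant difference, NA when not gated in) and
#'   `pairwise_p` matrix.
#' @export
compare_inputs <- function(summaries, alpha = 0.05) {
  if (length(summaries) < 2)
    stop("need at least 2 summaries to compare", call. = FALSE)
  accs <- lapply(summaries, function(s) {
    if (inherits(s, "cfi_replicates")) s$per_replicate$ACC else as.numeric(s)
  })
  labs <- names(accs)
  if (is.null(labs))
    labs <- vapply(seq_along(summaries), function(i) {
      s <- summaries[[i]]
      if (inherits(s, "cfi_replicates")) s$input else paste0("input", i)
    }, character(1))
  names(accs) <- labs
  n <- unique(lengths(accs))
  if (length(n) != 1)
    stop("unequal replicate counts; a balanced design is required",
         call. = FALSE)
  k <- length(accs)
  means <- vapply(accs, mean, numeric(1))
  ses <- vapply(accs, function(v) sd(v) / sqrt(length(v)), numeric(1))
  grand <- mean(unlist(accs))
  ssb <- n * sum((means - grand)^2)
  sse <- sum(vapply(accs, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- k - 1; dfe <- k * (n - 1)
  mse <- sse / dfe
  if (ssb <= 1e-10 * max(1, grand^2)) {
    fstat <- 0; pval <- 1
  } else if (sse <= 1e-10 * max(1, grand^2)) {
    fstat <- Inf; pval <- 0
  } else {
    fstat <- (ssb / dfb) / mse
    pval <- stats::pf(fstat, dfb, dfe, lower.tail = FALSE)
  }
  pw <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  lsd <- NA_real_
  if (pval < alpha) {
    lsd <- qt(1 - alpha / 2, dfe) * sqrt(2 * mse / n)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tstat <- abs(means[i] - means[j]) / sqrt(2 * mse / n)
      pw[i, j] <- pw[j, i] <- if (mse > 0) 2 * pt(-tstat, dfe)
                              else as.numeric(means[i] == means[j])
    }
    letters_vec <- .cld_letters(means, lsd)
  } else {
    letters_vec <- setNames(rep("a", k), labs)
  }
  ord <- order(means, decreasing = TRUE)
  structure(list(table = data.frame(input = labs[ord],
                                    mean = as.numeric(means[ord]),
                                    se = as.numeric(ses[ord]),
                                    letter = letters_vec[ord],
                                    row.names = NULL),
                 anova = list(F = fstat, p = pval, df = c(dfb, dfe),
                              MSE = mse),
                 lsd = lsd, pairwise_p = pw, alpha = alpha),
            class = "cfi_comparison")
}

# compact letter display for equal-n LSD: groups closer than `lsd` in
# mean are not significantly different, so maximal runs of the sorted
# means define the letter groups
.cld_letters <- function(means, lsd) {
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && abs(m[i] - m[j + 1]) < lsd) j <- j + 1
    runs[[length(runs) + 1]] <- seq(i, j)
  }
  keep <- !vapply(seq_along(runs), function(a)
    any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), logical(1))), logical(1))
  runs <- runs[keep]
  lab <- rep("", k)
  for (ri in seq_along(runs))
    lab[runs[[ri]]] <- paste0(lab[runs[[ri]]], letters[ri])
  out <- character(k)
  out[ord] <- lab
  setNames(out, names(means))
}

#' @export
print.cfi_comparison <- function(x, ...) {
  cat("<cfi_comparison> one-way ANOVA F = ", sprintf("%.2f", x$anova$F),
      " (df ", x$anova$df[1], ", ", x$anova$df[2], "), p = ",
      format.pval(x$anova$p, digits = 3), "\n", sep = "")
  if (!is.na(x$lsd))
    cat("  Fisher LSD at alpha = ", x$alpha, ": ",
        sprintf("%.2f", x$lsd), " percentage points\n", sep = "")
  tab <- x$table
  tab$mean <- sprintf("%.1f", tab$mean)
  tab$se <- sprintf("%.1f", tab$se)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cfi_comparison <- function(x, ...) {
  m <- x$table$mean; s <- x$table$se
  bp <- barplot(m, names.arg = x$table$input, ylim = c(0, 110),
                ylab = "mean ACC (%)", ...)
  arrows(bp, m - s, bp, m + s, angle = 90, code = 3, length = 0.05)
  text(bp, m + s + 4, x$table$letter)
  invisible(x)
}
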