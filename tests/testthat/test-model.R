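short_cfg <- function(...) {
  train_config(c_grid = 10^seq(-2, 2), cv_folds = 3, ...)
}

test_that("training configuration is validated", {
  expect_error(train_config(split_ratio = 0), "split_ratio")
  expect_error(train_config(c_grid = c(1e-5, 1)), "c_grid")
  expect_error(train_config(c_grid = c(1, 1e5)), "c_grid")
  expect_error(train_config(replicates = 0), "replicates")
})

test_that("stratified splits hit the target sizes and proportions", {
  labels <- rep(c("a", "b", "c"), c(40, 35, 25))
  sp <- split_data(labels, 0.6, seed = 5)
  expect_length(sp$train, 60)
  expect_length(sp$test, 40)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  # per-class proportion within one sample of the overall ratio
  for (cl in c("a", "b", "c")) {
    n_cl <- sum(labels == cl)
    expect_lte(abs(sum(labels[sp$train] == cl) - 0.6 * n_cl), 1)
  }
  expect_identical(split_data(labels, 0.6, seed = 5), sp)
  expect_false(identical(split_data(labels, 0.6, seed = 6)$train, sp$train))
  expect_error(split_data(rep(c("a", "b"), c(4, 40)), 0.6, seed = 1,
                          min_train = 5), "'a'")
})

test_that("well-separated classes are classified perfectly", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60, -5, 0.5), 30, 2),
             matrix(rnorm(60, 5, 0.5), 30, 2))
  y <- rep(c("n", "i"), each = 30)
  fit <- train_svm(x[c(1:20, 31:50), ], y[c(1:20, 31:50)], short_cfg())
  pred <- predict(fit, x[c(21:30, 51:60), ])
  expect_true(all(as.character(pred) == y[c(21:30, 51:60)]))
})

test_that("label-independent features yield chance-level accuracy", {
  set.seed(21)
  feats <- list(features = matrix(rnorm(80 * 10), 80, 10,
                                  dimnames = list(NULL, paste0("f", 1:10))),
                labels = rep(c(0, 1), each = 40), band = "fused")
  r <- run_replicates(feats, short_cfg(task = "two", replicates = 8,
                                       seed = 4))
  # majority rate 50%; binomial CI over 8 x 32 test predictions
  expect_gt(r$means["ACC"], 35)
  expect_lt(r$means["ACC"], 65)
})

test_that("the fitted hyperplane matches a direct primal minimisation", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40, -1, 1), 20, 2), matrix(rnorm(40, 1, 1), 20, 2))
  y <- factor(rep(c("a", "b"), each = 20))
  cost <- 1
  fit <- cfichill:::.svm_binary(x, y, cost)
  w_svm <- drop(t(fit$coefs) %*% fit$SV)
  b_svm <- -fit$rho
  # libsvm orients the decision toward the first label it sees ("a")
  ysgn <- ifelse(y == "a", 1, -1)
  primal <- function(p) {
    margins <- ysgn * (x %*% p[1:2] + p[3])
    0.5 * sum(p[1:2]^2) + cost * sum(pmax(0, 1 - margins))
  }
  opt <- optim(c(w_svm, b_svm) * 0, primal, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  opt <- optim(opt$par, primal, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lt(abs(primal(c(w_svm, b_svm)) - opt$value), 1e-4 * (1 + opt$value))
})

test_that("cross-validation ties resolve to the smallest cost", {
  set.seed(41)
  x <- rbind(matrix(rnorm(60, -8, 0.3), 30, 2),
             matrix(rnorm(60, 8, 0.3), 30, 2))
  y <- rep(c("n", "i"), each = 30)
  fit <- train_svm(x, y, short_cfg(seed = 2))
  expect_equal(fit$cost, min(short_cfg()$c_grid))
  expect_true(all(fit$cv$accuracy == 1))
})

test_that("one-vs-rest handles three separable classes", {
  set.seed(51)
  # non-collinear class centres so every one-vs-rest split is separable
  x <- rbind(cbind(rnorm(30, -8, 0.5), rnorm(30, -8, 0.5)),
             cbind(rnorm(30, 8, 0.5), rnorm(30, -8, 0.5)),
             cbind(rnorm(30, 0, 0.5), rnorm(30, 8, 0.5)))
  y <- rep(c("class0", "class1", "class2"), each = 30)
  fit <- train_svm(x, y, short_cfg(task = "three", seed = 3))
  expect_length(fit$fits, 3)
  expect_true(all(as.character(predict(fit, x)) == y))
  W <- coef(fit)
  expect_identical(dim(W), c(3L, 3L))  # 2 weights + bias per class
  expect_error(train_svm(x[1:30, ], y[1:30], short_cfg()), "single class")
})

test_that("replicated evaluation is seeded and degenerates correctly", {
  set.seed(61)
  x <- rbind(matrix(rnorm(200, -6, 0.5), 50, 4),
             matrix(rnorm(200, 6, 0.5), 50, 4))
  colnames(x) <- paste0("f", 1:4)
  feats <- list(features = x, labels = rep(c(0, 2), each = 50),
                band = "fused")
  cfg <- short_cfg(task = "two", replicates = 5, seed = 9)
  r1 <- run_replicates(feats, cfg)
  r2 <- run_replicates(feats, cfg)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_identical(nrow(r1$per_replicate), 5L)
  expect_equal(unname(r1$means["ACC"]), 100)
  expect_equal(unname(r1$se["ACC"]), 0)
  # ACC is recomputable from the stored confusion matrices
  for (k in seq_len(5)) {
    cm <- r1$confusions[[k]]
    expect_equal(100 * sum(diag(cm)) / sum(cm),
                 r1$per_replicate$ACC[k])
  }
})

test_that("training accuracy dominates test accuracy on average", {
  set.seed(71)
  x <- rbind(matrix(rnorm(300, -0.7, 1), 50, 6),
             matrix(rnorm(300, 0.7, 1), 50, 6))
  y <- factor(rep(c("n", "i"), each = 50), levels = c("n", "i"))
  tr_acc <- te_acc <- numeric(6)
  for (r in 1:6) {
    sp <- split_data(y, 0.6, seed = r, min_train = 3)
    std <- cfichill:::.standardize(x[sp$train, ], x)
    fit <- train_svm(std$all[sp$train, ], y[sp$train], short_cfg(),
                     fold_seed = r)
    tr_acc[r] <- mean(predict(fit, std$all[sp$train, ]) == y[sp$train])
    te_acc[r] <- mean(predict(fit, std$all[sp$test, ]) == y[sp$test])
  }
  expect_gte(mean(tr_acc), mean(te_acc))
})
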