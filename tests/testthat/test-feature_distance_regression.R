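make_condition_features <- function(n_cond, n_img, n_feat, seed,
                                    prefix = "c") {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_cond)) {
    f <- matrix(rnorm(n_img * n_feat), n_img, n_feat,
                dimnames = list(NULL, paste0("f", seq_len(n_feat))))
    out[[sprintf("%s%d_x", prefix, i)]] <- f
  }
  out
}

test_that("dataset assembly computes per-feature mean pairwise distances", {
  cf <- make_condition_features(2, 3, 3, seed = 1)
  y <- setNames(c(1.2, 0.4), names(cf))
  ds <- assemble_dataset(cf, y)
  expect_equal(dim(ds$X), c(2, 3))
  # oracle: explicit loop over unordered pairs
  f <- cf[[1]]
  want <- sapply(1:3, function(j)
    mean(c(abs(f[1, j] - f[2, j]), abs(f[1, j] - f[3, j]),
           abs(f[2, j] - f[3, j]))))
  expect_equal(unname(ds$X[1, ]), want, tolerance = 1e-12)
  # identical images give an all-zero row
  cf2 <- cf
  cf2[[2]] <- cf[[2]][c(1, 1, 1), ]
  expect_equal(unname(assemble_dataset(cf2, y)$X[2, ]), rep(0, 3))
  expect_error(assemble_dataset(cf, y[1]), "lacking")
})

test_that("stratified splits keep the task ratio and are seed-stable", {
  cf <- make_condition_features(30, 2, 4, seed = 2)
  names(cf) <- paste0(rep(paste0("t", 1:6), each = 5), "_", 1:30)
  y <- setNames(rnorm(30), names(cf))
  ds <- assemble_dataset(cf, y)
  expect_equal(sort(unique(ds$task)), paste0("t", 1:6))
  sp <- split_train_test(ds, seed = 11)
  expect_length(sp$train, 24)
  expect_length(sp$test, 6)
  expect_equal(as.integer(table(ds$task[sp$test])), rep(1L, 6))
  expect_identical(sp, split_train_test(ds, seed = 11))
  # each row lands in the test set about 20% of the time
  hits <- integer(30)
  for (s in 1:400)
    hits[split_train_test(ds, seed = s)$test] <-
      hits[split_train_test(ds, seed = s)$test] + 1L
  expect_true(all(abs(hits / 400 - 0.2) < 0.08))
})

test_that("small strata are pooled with a warning", {
  cf <- make_condition_features(12, 2, 3, seed = 3)
  names(cf) <- paste0(c(rep("big", 9), rep("tiny", 3)), "_", 1:12)
  y <- setNames(rnorm(12), names(cf))
  ds <- assemble_dataset(cf, y)
  expect_warning(sp <- split_train_test(ds, seed = 1), "pooled")
  expect_length(sp$test, round(12 * 0.2))
})

test_that("OLS matches a pseudo-inverse oracle and flags collinearity", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(0.5, 2, -1, 3)
  y <- beta[1] + X %*% beta[-1]
  co <- fit_ols(X, as.numeric(y))
  expect_equal(unname(co), beta, tolerance = 1e-10)   # zero residuals
  yn <- as.numeric(y + rnorm(20))
  expect_equal(unname(fit_ols(X, yn)), ols_pinv_oracle(X, yn),
               tolerance = 1e-8)
  Xc <- cbind(X, dup = X[, 1] * 2)
  expect_error(fit_ols(Xc, yn), "dup")
  expect_error(fit_ols(matrix(rnorm(8), 2, 4), rnorm(2)), "more predictors")
})

planted_dataset <- function(n = 75, p = 96, k_true = 5, snr = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta <- rep(0, p); beta[seq_len(k_true)] <- 2
  mu <- X %*% beta
  y <- as.numeric(mu + rnorm(n, sd = sd(mu) / snr))
  list(X = X, y = y, planted = paste0("f", seq_len(k_true)))
}

test_that("the fixed-support lasso returns exactly k nonzero coefficients", {
  pd <- planted_dataset(seed = 7)
  fit <- fit_lasso_fixed_support(pd$X, pd$y, k = 18, seed = 1)
  expect_equal(fit$k_achieved, 18)
  expect_length(fit$support, 18)
  expect_true(all(pd$planted %in% fit$support))
  # full shrinkage: the largest path lambda has an empty support
  g <- glmnet::glmnet(pd$X, pd$y)
  expect_equal(sum(abs(as.numeric(coef(g, s = max(g$lambda)))[-1]) > 0), 0)
})

test_that("planted supports are recovered across replicates", {
  hits <- 0
  for (r in 1:100) {
    pd <- planted_dataset(seed = 200 + r)
    fit <- fit_lasso_fixed_support(pd$X, pd$y, k = 18, seed = r,
                                   lambda_rule = "first")
    hits <- hits + all(pd$planted %in% fit$support)
  }
  expect_gte(hits, 90)
})

test_that("both lambda rules achieve the target support", {
  pd <- planted_dataset(seed = 30)
  f1 <- fit_lasso_fixed_support(pd$X, pd$y, k = 18, lambda_rule = "first")
  f2 <- fit_lasso_fixed_support(pd$X, pd$y, k = 18, lambda_rule = "cv_min")
  expect_equal(f1$k_achieved, 18)
  expect_equal(f2$k_achieved, 18)
})

make_regression_dataset <- function(X, y, tasks) {
  structure(list(X = X, y = y, task = tasks), class = "regression_dataset")
}

test_that("resampled evaluation is deterministic and behaves at the limits", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  tasks <- rep(paste0("t", 1:4), each = 10)
  y_lin <- as.numeric(1 + X %*% c(2, -1, 0.5, 0, 0, 0))
  ds <- make_regression_dataset(X, y_lin, tasks)
  r <- resample_evaluate(ds, "color_stats", n_resamples = 50, seed = 3)
  expect_equal(median(r$r2_distribution), 1, tolerance = 1e-8)
  expect_lt(max(r$mse_distribution), 1e-10)
  r2 <- resample_evaluate(ds, "color_stats", n_resamples = 50, seed = 3)
  expect_identical(r$mse_distribution, r2$mse_distribution)
  # null response: out-of-sample R2 is at or below zero
  ds_null <- make_regression_dataset(X, rnorm(n), tasks)
  rn <- resample_evaluate(ds_null, "color_stats", n_resamples = 100,
                          seed = 4)
  expect_lte(median(rn$r2_distribution), 0)
  expect_equal(nrow(rn$per_task_mse), 4)
  expect_true(all(rn$per_task_mse$ci_lo <= rn$per_task_mse$mse))
  expect_true(all(rn$per_task_mse$ci_hi >= rn$per_task_mse$mse))
})

test_that("fits never touch the test rows", {
  pd <- planted_dataset(n = 50, p = 20, seed = 9)
  tr <- 1:40
  co1 <- fit_ols(pd$X[tr, 1:10], pd$y[tr])
  f1 <- fit_lasso_fixed_support(pd$X[tr, ], pd$y[tr], k = 8, seed = 2)
  # perturb the held-out rows: nothing fitted on train may change
  pd$X[41:50, ] <- 99
  pd$y[41:50] <- -99
  expect_identical(co1, fit_ols(pd$X[tr, 1:10], pd$y[tr]))
  expect_identical(f1$coef,
                   fit_lasso_fixed_support(pd$X[tr, ], pd$y[tr], k = 8,
                                           seed = 2)$coef)
})

test_that("higher-order-statistic signal favors the richer feature set", {
  # planted model where only higher-order columns carry signal: the
  # 3-column "means" condition cannot fit it, the 96-column set can
  set.seed(10)
  n <- 75
  X_full <- matrix(rnorm(n * 96), n, 96,
                   dimnames = list(NULL, paste0("f", 1:96)))
  y <- as.numeric(X_full[, 10:14] %*% rep(2, 5) + rnorm(n, sd = 0.5))
  tasks <- rep(paste0("t", 1:5), each = 15)
  ds_means <- make_regression_dataset(X_full[, 1:3], y, tasks)
  ds_full <- make_regression_dataset(X_full, y, tasks)
  r_means <- resample_evaluate(ds_means, "color_means", n_resamples = 60,
                               seed = 5)
  r_full <- resample_evaluate(ds_full, "ps_color", n_resamples = 60,
                              seed = 5)
  expect_gt(median(r_means$mse_distribution),
            3 * median(r_full$mse_distribution))
  expect_gt(median(r_full$r2_distribution),
            median(r_means$r2_distribution))
})
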