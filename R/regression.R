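#' Assemble the sensitivity-on-feature-distance regression dataset
#'
#' One row per task condition. The predictors are per-feature distances:
#' `X[i, j]` is the mean over all unordered image pairs of condition `i`
#' of the absolute difference in feature `j` (per-feature distances let
#' the regression weight features; a single scalar distance could not).
#' The response is the condition's discrimination sensitivity d-prime.
#'
#' @param condition_features named list; element `i` is the feature
#'   matrix (rows = the condition's stimulus images) of condition `i`.
#' @param sensitivities named numeric vector of d-prime per condition;
#'   names must match `condition_features`.
#' @param task factor/character vector per condition (stratification
#'   unit); defaults to the part of each condition name before the first
#'   `"_"`.
#' @return List of class `regression_dataset`: `X` (matrix), `y`, `task`.
#' @export
assemble_dataset <- function(condition_features, sensitivities,
                             task = NULL) {
  if (is.null(names(condition_features)) || is.null(names(sensitivities)))
    stop("condition_features and sensitivities must be named")
  gap <- setdiff(names(condition_features), names(sensitivities))
  if (length(gap))
    stop("conditions lacking a sensitivity: ", paste(gap, collapse = ", "))
  gap2 <- setdiff(names(sensitivities), names(condition_features))
  if (length(gap2))
    stop("conditions lacking features: ", paste(gap2, collapse = ", "))
  ids <- names(condition_features)
  X <- t(vapply(ids, function(id) {
    f <- condition_features[[id]]
    stopifnot(is.matrix(f), nrow(f) >= 2)
    prs <- utils::combn(nrow(f), 2)
    colMeans(abs(f[prs[1, ], , drop = FALSE] - f[prs[2, ], , drop = FALSE]))
  }, numeric(ncol(condition_features[[1]]))))
  colnames(X) <- colnames(condition_features[[1]])
  rownames(X) <- ids
  if (is.null(task)) task <- sub("_.*$", "", ids)
  if (any(!is.finite(X)) || any(!is.finite(sensitivities[ids])))
    stop("dataset contains non-finite values")
  structure(list(X = X, y = unname(sensitivities[ids]), task = task),
            class = "regression_dataset")
}

#' Stratified train/test split with a fixed ratio
#'
#' Splits conditions 4:1 into training and test sets while keeping the
#' per-task row ratio constant: within each stratum the test count is
#' allocated by the largest-remainder rule on `n_i * ratio`. Strata with
#' fewer than 5 rows are pooled into one stratum with a warning.
#'
#' @param dataset a [assemble_dataset()] result.
#' @param ratio test fraction (default 0.2, i.e. a 4:1 split).
#' @param seed integer seed.
#' @return List with `train` and `test` row indices.
#' @export
split_train_test <- function(dataset, ratio = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "regression_dataset"), ratio > 0, ratio < 1)
  task <- dataset$task
  n <- length(dataset$y)
  small <- names(which(table(task) < 5))
  if (length(small)) {
    warning("strata smaller than 5 pooled: ", paste(small, collapse = ", "))
    task[task %in% small] <- ".pooled"
  }
  strata <- split(seq_len(n), task)
  want <- vapply(strata, length, integer(1)) * ratio
  base <- floor(want)
  rem <- round(sum(want)) - sum(base)
  if (rem > 0) {
    # largest remainders get the leftover test slots
    extra <- order(want - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  test <- with_seed(seed, unlist(lapply(seq_along(strata), function(i) {
    if (base[i] == 0) return(integer(0))
    sample(strata[[i]], base[i])
  }), use.names = FALSE))
  list(train = sort(setdiff(seq_len(n), test)), test = sort(test))
}

#' Ordinary least squares with intercept
#'
#' @param X predictor matrix (columns <= rows, full rank).
#' @param y response.
#' @return Named coefficient vector (`(Intercept)` first).
#' @export
fit_ols <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (ncol(X) > nrow(X)) stop("more predictors than observations")
  Xi <- cbind("(Intercept)" = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    drop_cols <- colnames(Xi)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  stats::setNames(qr.coef(qrx, y), c("(Intercept)", colnames(X)))
}

#' Lasso with a fixed support size
#'
#' L1-penalized least squares whose penalty is tuned so the fitted model
#' has exactly `k` nonzero coefficients: the glmnet regularization path
#' is searched, refined by bisection on lambda where the path's support
#' size jumps over `k`, and if several lambdas achieve support `k` the
#' one with the best `cv_folds`-fold cross-validated MSE inside the
#' training data is chosen (`lambda_rule = "cv_min"`) or the largest
#' such lambda (`"first"`). If no lambda achieves exactly `k` (the
#' support jumps past it), the nearest support below `k` is used with a
#' warning. Predictors are standardized internally on the supplied
#' (training) data only.
#'
#' @param X training predictor matrix; `k < ncol(X)`.
#' @param y training response.
#' @param k target number of nonzero coefficients (default 18).
#' @param cv_folds folds for the cross-validated choice among candidate
#'   lambdas.
#' @param seed integer seed (fold assignment).
#' @param lambda_rule `"cv_min"` or `"first"`.
#' @return List of class `fixed_support_fit`: `coef` (named, with
#'   intercept), `support` (feature names), `lambda`, `k_achieved`.
#' @export
fit_lasso_fixed_support <- function(X, y, k = 18, cv_folds = 5, seed = 1L,
                                    lambda_rule = c("cv_min", "first")) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(X), nrow(X) == length(y), k >= 1, k < ncol(X))
  fit <- glmnet::glmnet(X, y, alpha = 1, nlambda = 200,
                        lambda.min.ratio = 1e-4)
  coef_at <- function(lam)  # exact refit, not path interpolation
    as.numeric(stats::coef(fit, s = lam, exact = TRUE, x = X, y = y))
  nz_at <- function(lam) sum(abs(coef_at(lam)[-1]) > 0)
  df <- fit$df
  lams <- fit$lambda
  cand <- lams[df == k]
  if (!length(cand)) {
    # bisect between the bracketing path points where support jumps past k
    below <- which(df < k); above <- which(df > k)
    if (length(below) && length(above)) {
      lo <- lams[min(above)]          # smaller lambda, support > k
      hi <- lams[max(below)]          # larger lambda, support < k
      for (it in 1:40) {
        mid <- sqrt(lo * hi)          # lambda is log-scaled
        nzm <- nz_at(mid)
        if (nzm == k) { cand <- mid; break }
        if (nzm < k) hi <- mid else lo <- mid
      }
    }
  }
  if (!length(cand)) {
    # support jumps over k: take the nearest support below k
    k_below <- max(df[df < k], 0)
    cand <- if (any(df == k_below)) lams[df == k_below] else max(lams)
    warning(sprintf(
      "no lambda achieves support %d; using nearest support below (%d)",
      k, k_below))
  }
  lam <- if (length(cand) == 1 || lambda_rule == "first") {
    max(cand)
  } else {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(X))))
    cvm <- vapply(cand, function(l) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- foldid != f
        g <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = 1,
                            lambda = l)
        mean((y[!tr] - as.numeric(stats::predict(g, X[!tr, , drop = FALSE],
                                                 s = l)))^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    cand[which.min(cvm)]
  }
  beta <- coef_at(lam)
  names(beta) <- c("(Intercept)", colnames(X))
  support <- names(beta)[-1][abs(beta[-1]) > 0]
  structure(list(coef = beta, support = support, lambda = lam,
                 k_achieved = length(support)),
            class = "fixed_support_fit")
}

# predict from a named coefficient vector (intercept first)
predict_linear <- function(coefs, X) {
  beta <- coefs[-1]
  used <- names(beta)[beta != 0]
  as.numeric(coefs[1] + X[, used, drop = FALSE] %*% beta[used])
}

#' Resampled train/test evaluation of one regression condition
#'
#' For each resample: stratified 4:1 split, fit (OLS for the
#' `color_means`/`color_stats` conditions, fixed-support lasso for the
#' PS-statistics conditions), and evaluation of test MSE and test
#' R-squared (1 - SS_res/SS_tot about the test mean; can be negative).
#' Per-task test MSE is accumulated across resamples with percentile
#' bootstrap 95% confidence intervals.
#'
#' @param dataset a [assemble_dataset()] result whose `X` columns are the
#'   condition's feature set.
#' @param condition_name one of `"color_means"`, `"color_stats"`,
#'   `"ps_gray"`, `"ps_gray_plus_color"`, `"ps_color"`.
#' @param n_resamples number of resampled splits (the study default is
#'   10000; smaller values keep exploratory runs fast).
#' @param k lasso support size for the penalized conditions.
#' @param seed master seed; each resample derives its own split seed.
#' @param lambda_rule passed to [fit_lasso_fixed_support()].
#' @return List of class `regression_result`: `condition_name`,
#'   `mse_distribution`, `r2_distribution`, `per_task_mse` (data frame
#'   with bootstrap 95% CIs), `support_counts` (penalized fits only).
#' @export
resample_evaluate <- function(dataset, condition_name, n_resamples = 500,
                              k = 18, seed = 1L,
                              lambda_rule = "cv_min") {
  stopifnot(inherits(dataset, "regression_dataset"))
  penalized <- condition_name %in% c("ps_gray", "ps_gray_plus_color",
                                     "ps_color")
  mse <- r2 <- numeric(n_resamples)
  task_names <- sort(unique(dataset$task))
  task_sums <- matrix(0, n_resamples, length(task_names),
                      dimnames = list(NULL, task_names))
  task_n <- task_sums
  supports <- integer(0)
  for (b in seq_len(n_resamples)) {
    sp <- split_train_test(dataset, seed = derive_seed(seed, "split", b))
    Xtr <- dataset$X[sp$train, , drop = FALSE]
    ytr <- dataset$y[sp$train]
    Xte <- dataset$X[sp$test, , drop = FALSE]
    yte <- dataset$y[sp$test]
    coefs <- if (penalized) {
      f <- fit_lasso_fixed_support(Xtr, ytr, k = k,
                                   seed = derive_seed(seed, "cv", b),
                                   lambda_rule = lambda_rule)
      supports <- c(supports, list(f$support))
      f$coef
    } else {
      fit_ols(Xtr, ytr)
    }
    pred <- predict_linear(coefs, Xte)
    err2 <- (yte - pred)^2
    mse[b] <- mean(err2)
    ss_tot <- sum((yte - mean(yte))^2)
    r2[b] <- if (ss_tot > 0) 1 - sum(err2) / ss_tot else NA_real_
    tt <- dataset$task[sp$test]
    for (tk in unique(tt)) {
      task_sums[b, tk] <- sum(err2[tt == tk])
      task_n[b, tk] <- sum(tt == tk)
    }
  }
  per_task <- do.call(rbind, lapply(task_names, function(tk) {
    per <- task_sums[, tk] / pmax(task_n[, tk], 1)
    per <- per[task_n[, tk] > 0]
    data.frame(task = tk, mse = mean(per),
               ci_lo = unname(stats::quantile(per, 0.025)),
               ci_hi = unname(stats::quantile(per, 0.975)),
               stringsAsFactors = FALSE)
  }))
  structure(list(condition_name = condition_name,
                 mse_distribution = mse, r2_distribution = r2,
                 per_task_mse = per_task,
                 support_counts = if (penalized)
                   sort(table(unlist(supports)), decreasing = TRUE)
                 else NULL),
            class = "regression_result")
}
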