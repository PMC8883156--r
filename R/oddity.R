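#' Oddity-task design
#'
#' An m-alternative oddity trial presents `m` stimuli of which one (the
#' target) differs; the observer picks the odd one. With four alternatives
#' the chance level is 0.25, with three it is 0.33.
#'
#' @param m number of alternatives, 3 or 4.
#' @param n_sim Monte-Carlo trials used per psychometric point.
#' @param seed integer seed for the Monte-Carlo stream.
#' @return A list of class `oddity_design` with fields `m`, `chance`
#'   (`1/m`), `n_sim`, `seed`.
#' @export
oddity_design <- function(m, n_sim = 1e5, seed = 1L) {
  if (!m %in% c(3, 4)) stop("m must be 3 or 4")
  structure(list(m = as.integer(m), chance = 1 / m,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "oddity_design")
}

# Differencing decision rule for one or more oddity trials.
# x: n_trials x m matrix of internal responses (target in column `target`).
# The simulated observer picks the sample farthest from the mean of the
# remaining m-1 samples; since |x_j - mean(x_{-j})| = m/(m-1) |x_j - xbar|,
# this equals picking the sample farthest from the grand mean.
# Returns the chosen column index per row.
oddity_choose <- function(x) {
  dev <- abs(x - rowMeans(x))
  max.col(dev, ties.method = "first")
}

#' Simulate the oddity psychometric function at a given sensitivity
#'
#' Monte-Carlo simulation of the unbiased differencing observer under
#' equal-variance Gaussian noise: on each trial the `m - 1` non-targets are
#' standard normal draws, the target is normal with mean `d_prime`, and the
#' observer chooses the sample most distant from the mean of the remaining
#' samples. The fraction of trials on which the target is chosen estimates
#' the proportion correct.
#'
#' @param d_prime sensitivity, nonnegative.
#' @param design an [oddity_design()].
#' @return Proportion correct in `[0, 1]`.
#' @examples
#' simulate_oddity_pc(0, oddity_design(4))   # ~0.25
#' simulate_oddity_pc(2, oddity_design(3))
#' @export
simulate_oddity_pc <- function(d_prime, design) {
  stopifnot(inherits(design, "oddity_design"), d_prime >= 0)
  m <- design$m
  n <- design$n_sim
  with_seed(design$seed, {
    x <- matrix(stats::rnorm(n * m), n, m)
    x[, 1L] <- x[, 1L] + d_prime
    mean(oddity_choose(x) == 1L)
  })
}

#' Finite-trial ceiling correction for proportion correct
#'
#' A proportion correct of exactly 1 maps to infinite d-prime; following
#' standard practice the value 1 is replaced by `1 - 1/(2 * n_trials)`.
#' Values below the ceiling are returned unchanged.
#'
#' @param pc proportion correct in `[0, 1]` (vectorized).
#' @param n_trials number of trials the proportion is based on (>= 1).
#' @return Corrected proportion, strictly below 1.
#' @export
correct_pc <- function(pc, n_trials) {
  if (any(n_trials < 1)) stop("n_trials must be >= 1")
  stopifnot(all(pc >= 0), all(pc <= 1))
  pmin(pc, 1 - 1 / (2 * n_trials))
}

# Monotone psychometric lookup for a design: simulates pc on a d' grid with
# common random numbers, enforces monotonicity, and returns interpolating
# functions. Cached per (m, n_sim, seed).
psychometric_lookup <- function(design, d_max = 8, step = 0.25) {
  key <- sprintf("pml_%d_%d_%d", design$m, design$n_sim, design$seed)
  if (!is.null(.matodd_cache[[key]])) return(.matodd_cache[[key]])
  dgrid <- seq(0, d_max, by = step)
  pc <- vapply(dgrid, simulate_oddity_pc, numeric(1), design = design)
  # common random numbers make pc near-monotone; enforce exactly
  pc <- cummax(pc)
  keep <- !duplicated(pc)
  dgrid <- dgrid[keep]; pc <- pc[keep]
  fwd <- stats::splinefun(dgrid, pc, method = "hyman")
  lut <- list(dgrid = dgrid, pc = pc, fwd = fwd, d_max = d_max)
  .matodd_cache[[key]] <- lut
  lut
}

#' Convert proportion correct to oddity-task sensitivity (d-prime)
#'
#' Applies the finite-trial correction, then inverts a simulated
#' psychometric function: `simulate_oddity_pc` is evaluated on a d-prime
#' grid with a fixed seed, a shape-preserving monotone interpolant is built
#' through the simulated points, and the corrected proportion is inverted
#' by bisection. Proportions at or below chance map to d-prime 0 (the
#' floor convention: no negative sensitivities).
#'
#' @param pc proportion correct in `[0, 1]`.
#' @param design an [oddity_design()].
#' @param n_trials trial count behind `pc`, used by the ceiling correction.
#' @return A list of class `sensitivity_estimate`: `pc` (corrected),
#'   `n_trials`, `chance`, `d_prime`.
#' @export
pc_to_dprime <- function(pc, design, n_trials) {
  stopifnot(inherits(design, "oddity_design"), pc >= 0, pc <= 1)
  pc_c <- correct_pc(pc, n_trials)
  lut <- psychometric_lookup(design)
  if (pc_c <= design$chance) {
    dp <- 0
  } else if (pc_c >= max(lut$pc)) {
    dp <- lut$d_max
  } else {
    dp <- stats::uniroot(function(d) lut$fwd(d) - pc_c,
                         lower = 0, upper = lut$d_max,
                         tol = 1e-8)$root
  }
  structure(list(pc = pc_c, n_trials = n_trials, chance = design$chance,
                 d_prime = max(dp, 0)),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("pc = %.3f (N = %d, chance = %.2f) -> d' = %.3f\n",
              x$pc, x$n_trials, x$chance, x$d_prime))
  invisible(x)
}

#' Aggregate oddity responses into per-condition sensitivity estimates
#'
#' Two aggregation modes mirror the two experimental environments:
#' `per_observer` (laboratory: each observer contributes several
#' repetitions, so d-prime is computed per observer and then averaged, with
#' the SEM across observers) and `pooled` (crowdsourcing: each observer
#' contributes one trial per condition, so a single proportion correct is
#' computed over all observers and converted once).
#'
#' @param records data frame of trial records with columns `observer_id`,
#'   `task`, `illumination_condition`, `object`, `difficulty`, `m`,
#'   `correct` (logical or 0/1). Unequal per-observer trial counts are
#'   allowed.
#' @param mode `"per_observer"` or `"pooled"`.
#' @param n_sim,seed Monte-Carlo settings for the psychometric inversion.
#' @return Data frame with one row per (task, illumination_condition,
#'   object, difficulty): `pc`, `n_trials`, `d_prime`, and for
#'   `per_observer` additionally `sem` (SD of per-observer d-primes /
#'   sqrt(n_observers)) and `n_observers`.
#' @export
aggregate_sensitivity <- function(records,
                                  mode = c("per_observer", "pooled"),
                                  n_sim = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  need <- c("observer_id", "task", "illumination_condition", "object",
            "difficulty", "m", "correct")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0) stop("records is empty")
  records$correct <- as.logical(records$correct)
  key <- interaction(records$task, records$illumination_condition,
                     records$object, records$difficulty, drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    des <- oddity_design(g$m[1], n_sim = n_sim, seed = seed)
    base <- data.frame(task = g$task[1],
                       illumination_condition = g$illumination_condition[1],
                       object = g$object[1], difficulty = g$difficulty[1],
                       stringsAsFactors = FALSE)
    if (mode == "pooled") {
      est <- pc_to_dprime(mean(g$correct), des, n_trials = nrow(g))
      cbind(base, pc = est$pc, n_trials = est$n_trials,
            d_prime = est$d_prime)
    } else {
      per <- vapply(split(g$correct, g$observer_id), function(cc)
        pc_to_dprime(mean(cc), des, n_trials = length(cc))$d_prime,
        numeric(1))
      cbind(base, pc = mean(g$correct), n_trials = nrow(g),
            d_prime = mean(per),
            sem = stats::sd(per) / sqrt(length(per)),
            n_observers = length(per))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-observer accuracy summary
#'
#' Averages each observer's responses across objects and task difficulties
#' within a (task, illumination condition) cell, giving the per-observer
#' accuracy distribution whose spread indexes individual differences.
#'
#' @param records trial records as in [aggregate_sensitivity()].
#' @return Data frame with columns `task`, `illumination_condition`,
#'   `observer_id`, `accuracy`, plus per-cell `mean_accuracy` and
#'   `sd_accuracy` repeated on each row.
#' @export
observer_accuracy <- function(records) {
  records$correct <- as.logical(records$correct)
  key <- interaction(records$task, records$illumination_condition,
                     records$observer_id, drop = TRUE)
  acc <- do.call(rbind, lapply(split(records, key), function(g)
    data.frame(task = g$task[1],
               illumination_condition = g$illumination_condition[1],
               observer_id = g$observer_id[1],
               accuracy = mean(g$correct), stringsAsFactors = FALSE)))
  cell <- interaction(acc$task, acc$illumination_condition, drop = TRUE)
  acc$mean_accuracy <- stats::ave(acc$accuracy, cell)
  acc$sd_accuracy <- stats::ave(acc$accuracy, cell,
                                FUN = function(v) stats::sd(v))
  rownames(acc) <- NULL
  acc
}

#' Regress crowdsourced sensitivity on laboratory sensitivity
#'
#' Ordinary least squares of crowd d-prime on lab d-prime across matched
#' task conditions; the slope below 1 quantifies the attenuation of
#' sensitivity in the uncontrolled environment and R-squared its
#' cross-environment consistency.
#'
#' @param lab,crowd paired numeric vectors of per-condition d-prime.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
cross_environment_regression <- function(lab, crowd) {
  stopifnot(length(lab) == length(crowd))
  ok <- is.finite(lab) & is.finite(crowd)
  lab <- lab[ok]; crowd <- crowd[ok]
  if (length(lab) < 3) stop("need at least 3 finite pairs")
  fit <- stats::lm(crowd ~ lab)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(lab))
}
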