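test_that("oddity proportion correct equals chance at zero sensitivity", {
  for (m in c(3, 4)) {
    des <- oddity_design(m, n_sim = 1e6, seed = 7L)
    pc <- simulate_oddity_pc(0, des)
    se <- sqrt((1 / m) * (1 - 1 / m) / 1e6)
    expect_lt(abs(pc - 1 / m), 3 * se)
  }
})

test_that("oddity proportion correct saturates at high sensitivity", {
  expect_gt(simulate_oddity_pc(8, oddity_design(3, n_sim = 1e5)), 0.99)
})

test_that("Monte-Carlo psychometric function matches the quadrature oracle", {
  des <- oddity_design(3, n_sim = 1e6, seed = 11L)
  for (d in c(0.5, 1, 1.5, 2, 4)) {
    mc <- simulate_oddity_pc(d, des)
    qd <- oddity_pc_quadrature_m3(d)
    expect_lt(abs(mc - qd), 0.005)
  }
})

test_that("psychometric function is monotone in sensitivity", {
  for (m in c(3, 4)) {
    des <- oddity_design(m, n_sim = 1e6, seed = 3L)
    pcs <- vapply(seq(0, 4, by = 0.5), simulate_oddity_pc, numeric(1),
                  design = des)
    expect_true(all(diff(pcs) > 0))
  }
})

test_that("finite-trial correction follows 1 - 1/(2N)", {
  expect_equal(correct_pc(1.0, 10), 0.95)
  expect_equal(correct_pc(0.7, 10), 0.7)
  expect_equal(correct_pc(1.0, 1), 0.5)
  expect_error(correct_pc(0.5, 0), "n_trials")
})

test_that("pc_to_dprime floors at chance and never returns pc of 1", {
  des <- oddity_design(4, n_sim = 1e5, seed = 5L)
  est <- pc_to_dprime(0.25, des, n_trials = 10)
  expect_equal(est$d_prime, 0)
  expect_equal(pc_to_dprime(0.1, des, 10)$d_prime, 0)
  est1 <- pc_to_dprime(1.0, des, n_trials = 10)
  expect_lt(est1$pc, 1)
  expect_gt(est1$d_prime, 0)
})

test_that("psychometric inversion round-trips within 0.01", {
  for (m in c(3, 4)) {
    des <- oddity_design(m, n_sim = 1e5, seed = 5L)
    for (p in seq(1 / m + 0.06, 0.95, by = 0.1)) {
      dp <- pc_to_dprime(p, des, n_trials = 1e6)$d_prime
      expect_lt(abs(simulate_oddity_pc(dp, des) - p), 0.01)
    }
  }
})

test_that("d-prime estimates are nondecreasing in proportion correct", {
  des <- oddity_design(3, n_sim = 1e5, seed = 5L)
  ps <- seq(0.2, 0.98, by = 0.02)
  dps <- vapply(ps, function(p) pc_to_dprime(p, des, 1e5)$d_prime, numeric(1))
  expect_true(all(diff(dps) >= 0))
})

make_records <- function(n_obs, n_rep, pc, m, seed, task = "GC") {
  set.seed(seed)
  data.frame(observer_id = rep(seq_len(n_obs), each = n_rep),
             task = task, illumination_condition = 1L, object = 1L,
             difficulty = 1L, m = m,
             correct = runif(n_obs * n_rep) < pc)
}

test_that("aggregation returns zero sensitivity for chance-level responding", {
  # every observer exactly at chance: 2 of 8 correct under m = 4
  rec <- make_records(20, 8, pc = 0, m = 4, seed = 2)
  rec$correct <- rep(c(TRUE, TRUE, rep(FALSE, 6)), 20)
  pooled <- aggregate_sensitivity(rec, "pooled")
  perobs <- aggregate_sensitivity(rec, "per_observer")
  expect_equal(pooled$d_prime, 0)
  expect_equal(perobs$d_prime, 0)
  expect_equal(perobs$n_observers, 20)
})

test_that("pooled crowd aggregation recovers a known generating d-prime", {
  des <- oddity_design(3, n_sim = 1e6, seed = 9L)
  pc_true <- simulate_oddity_pc(1.0, des)
  n_obs <- 400
  rec <- make_records(n_obs, 1, pc = pc_true, m = 3, seed = 31)
  est <- aggregate_sensitivity(rec, "pooled")
  # bootstrap CI of the pooled estimate
  set.seed(99)
  boot <- replicate(200, {
    idx <- sample.int(n_obs, replace = TRUE)
    pc_to_dprime(mean(rec$correct[idx]), oddity_design(3), n_obs)$d_prime
  })
  ci <- quantile(boot, c(0.025, 0.975))
  expect_gte(1.0, ci[1])
  expect_lte(1.0, ci[2])
  expect_lt(abs(est$d_prime - 1.0), 0.35)
})

test_that("unequal per-observer trial counts are accepted", {
  rec2 <- make_records(3, 7, 0.8, 3, 8)
  rec2$observer_id <- rec2$observer_id + 17L
  rec <- rbind(make_records(17, 10, 0.8, 3, 4), rec2)
  est <- aggregate_sensitivity(rec, "per_observer")
  expect_equal(est$n_observers, 20)
  expect_equal(est$n_trials, 17 * 10 + 3 * 7)
})

test_that("per-observer accuracy summary reproduces the generating spread", {
  set.seed(12)
  n_obs <- 300
  true_acc <- pmin(pmax(rnorm(n_obs, 0.7, 0.15), 0.05), 0.98)
  rec <- do.call(rbind, lapply(seq_len(n_obs), function(i)
    data.frame(observer_id = i, task = "GP", illumination_condition = 1L,
               object = 1:30 %% 5 + 1, difficulty = 1L, m = 4L,
               correct = runif(30) < true_acc[i])))
  acc <- observer_accuracy(rec)
  expect_equal(nrow(acc), n_obs)
  expect_lt(abs(acc$mean_accuracy[1] - mean(true_acc)), 0.02)
  # observed SD = generating SD plus binomial noise, approximately
  expected_sd <- sqrt(var(true_acc) + mean(true_acc * (1 - true_acc)) / 30)
  expect_lt(abs(acc$sd_accuracy[1] - expected_sd), 0.03)
})

test_that("cross-environment regression recovers slope and R-squared", {
  x <- seq(0, 3, length.out = 25)
  fit <- suppressWarnings(cross_environment_regression(x, x))
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  set.seed(5)
  y <- 0.5 * x + rnorm(25, sd = 1e-6)
  expect_equal(suppressWarnings(cross_environment_regression(x, y))$slope,
               0.5, tolerance = 1e-4)
  expect_error(cross_environment_regression(c(1, 2), c(1, 2)), "3")
})

test_that("a planted crowd attenuation factor is recovered", {
  set.seed(21)
  lab_d <- runif(40, 0.2, 3)
  des <- oddity_design(3, n_sim = 1e6, seed = 13L)
  crowd_rec <- do.call(rbind, lapply(seq_along(lab_d), function(i) {
    pc <- simulate_oddity_pc(0.7 * lab_d[i], des)
    make_records(120, 1, pc, 3, seed = 100 + i, task = paste0("c", i))
  }))
  crowd_est <- aggregate_sensitivity(crowd_rec, "pooled")
  crowd_d <- crowd_est$d_prime[match(paste0("c", seq_along(lab_d)),
                                     crowd_est$task)]
  fit <- cross_environment_regression(lab_d, crowd_d)
  se <- summary(stats::lm(crowd_d ~ lab_d))$coefficients[2, 2]
  expect_lt(abs(fit$slope - 0.7), 2.5 * se + 0.05)
  expect_gt(fit$r_squared, 0.6)
})
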