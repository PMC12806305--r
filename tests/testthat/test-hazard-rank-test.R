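# Nelson-Aalen hazard estimation and the bootstrap rank test: exact
# fixtures, an independent survival-package oracle, invariants, null
# behaviour and power at the generator defaults.

test_that("Nelson-Aalen fixtures match hand-computed rational values", {
  r <- survival_records(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(estimate_hazard(r, tau = 3), (1/3 + 1/1) / 3)  # 4/9

  # tie between a death and a censoring at t=1: deaths first, Y = 2
  r2 <- survival_records(c(1, 1), c(TRUE, FALSE))
  expect_equal(estimate_hazard(r2, tau = 2), (1/2) / 2)

  # two deaths tied at one time: summed before decrementing the risk set
  r3 <- survival_records(c(1, 1, 2), c(TRUE, TRUE, FALSE))
  expect_equal(estimate_hazard(r3, tau = 2), (2/3) / 2)

  # no CVD deaths -> zero hazard
  r4 <- survival_records(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_equal(estimate_hazard(r4, tau = 3), 0)

  # all n die of CVD at the same time: H = n/n = 1, result 1/tau
  r5 <- survival_records(rep(2, 7), rep(TRUE, 7))
  expect_equal(estimate_hazard(r5, tau = 4), 1 / 4)

  # events after tau do not contribute
  expect_equal(estimate_hazard(r, tau = 1.5), (1/3) / 1.5)

  expect_error(estimate_hazard(r[0, ], 1), "non-empty")
  expect_error(estimate_hazard(r, 0), "tau")
})

test_that("cumulative hazard agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:5) {
    time <- round(rexp(60, 0.4), 2) + 0.01  # rounding forces ties; keep > 0
    dead <- runif(60) < 0.6
    tau <- max(time)
    fit <- survival::survfit(survival::Surv(time, dead) ~ 1)
    H_ref <- max(c(0, fit$cumhaz))
    expect_equal(estimate_hazard(survival_records(time, dead), tau),
                 H_ref / tau, tolerance = 1e-12)
  }
})

test_that("adding a CVD death never decreases the estimated hazard", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    time <- rexp(n, 0.5)
    dead <- runif(n) < 0.5
    tau <- max(time)
    h0 <- estimate_hazard(survival_records(time, dead), tau)
    cens <- which(!dead)
    if (!length(cens)) next
    flip <- cens[sample.int(length(cens), 1)]
    dead2 <- dead; dead2[flip] <- TRUE
    h1 <- estimate_hazard(survival_records(time, dead2), tau)
    expect_gte(h1, h0)
  }
})

test_that("subgroup split uses the sign rule with zero in the increase group", {
  arm <- data.frame(pct_chol_change = c(-1, 0, 2), time = c(1, 2, 3),
                    event = c("cvd_death", "censored", "other_death"))
  sub <- split_subgroups(arm)
  expect_equal(nrow(sub$decrease), 1)
  expect_equal(nrow(sub$increase), 2)
  # only cvd_death counts as an event
  expect_equal(sub$decrease$is_cvd_death, TRUE)
  expect_equal(sub$increase$is_cvd_death, c(FALSE, FALSE))
})

test_that("other-cause deaths are censored (recoded), not deleted", {
  arm <- data.frame(pct_chol_change = c(-1, -2, -3, 1, 2),
                    time = c(1, 2, 3, 1, 2),
                    event = c("cvd_death", "other_death", "cvd_death",
                              "cvd_death", "censored"))
  sub <- split_subgroups(arm)
  # recoding keeps the other-death subject in the risk set at t=1:
  # H(3) = 1/3 + 1/1; deleting it would give 1/2 + 1/1
  expect_equal(estimate_hazard(sub$decrease, 3), (1/3 + 1) / 3)
  deleted <- sub$decrease[sub$decrease$is_cvd_death | sub$decrease$time > 2, ]
  expect_equal(estimate_hazard(deleted, 3), (1/2 + 1) / 3)
})

test_that("hazard difference is antisymmetric and the p-value two-tailed", {
  a <- survival_records(c(1, 2, 3), c(TRUE, TRUE, FALSE))
  b <- survival_records(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(hazard_difference(a, b), -hazard_difference(b, a))
  expect_equal(hazard_difference(a, a), 0)

  h_sim <- c(-0.2, 0.05, 0.15, -0.01)
  expect_equal(rank_test_p_value(0.1, h_sim), 0.5)
  expect_equal(rank_test_p_value(-0.1, -h_sim), 0.5)  # sign-flip invariant
  expect_equal(rank_test_p_value(0, h_sim), 1)
  expect_equal(rank_test_p_value(0.5, h_sim), 0)
  expect_error(rank_test_p_value(0.1, numeric(0)), "non-empty")
})

test_that("bootstrap null is centred, deterministic and degenerate-safe", {
  set.seed(88)
  pooled <- survival_records(rexp(120, 0.5), runif(120) < 0.4)
  h1 <- bootstrap_null(pooled, 60, 60, n_boot = 400, tau = 3, seed = 12)
  h2 <- bootstrap_null(pooled, 60, 60, n_boot = 400, tau = 3, seed = 12)
  expect_identical(h1, h2)
  expect_lt(abs(mean(h1)), 3 * sd(h1) / sqrt(length(h1)))

  none <- survival_records(rexp(30, 0.5), rep(FALSE, 30))
  expect_true(all(bootstrap_null(none, 15, 15, n_boot = 50, tau = 2, seed = 1) == 0))
})

test_that("run_scenario2 errors on empty subgroups, naming the subgroup", {
  coh <- mce_fixture(c(-5, -3), c(-2, -1),
                     time = rep(1, 4), event = rep("censored", 4))
  expect_error(run_scenario2(coh, "diet", n_boot = 10), "increase subgroup")
  coh2 <- mce_fixture(c(5, 3), c(2, 1), time = rep(1, 4),
                      event = rep("censored", 4))
  expect_error(run_scenario2(coh2, "control", n_boot = 10), "decrease subgroup")
})

test_that("type-I error of the rank test is calibrated at alpha = 0.05", {
  set.seed(404)
  rej <- replicate(500, {
    coh <- generate_mce(mce_config(
      n_diet = 150, n_control = 150,
      cvd_hazard_diet_decrease = 0.12, cvd_hazard_diet_increase = 0.12,
      seed = sample.int(1e8, 1)))
    run_scenario2(coh, "diet", n_boot = 300,
                  seed = sample.int(1e8, 1))$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("at generator defaults the diet arm has far lower power than the control arm", {
  # Calibration puts the control-arm difference ~10 null SDs out (rejects
  # essentially always) while the diet-arm difference sits ~1.8 null SDs
  # out, a borderline test whose per-seed rejection probability is ~0.45.
  res <- vapply(1:20, function(s) {
    coh <- generate_mce(mce_config(seed = 700 + s))
    c(ctrl = run_scenario2(coh, "control", n_boot = 500, seed = s)$p_value,
      diet = run_scenario2(coh, "diet", n_boot = 500, seed = s)$p_value)
  }, numeric(2))
  expect_gte(mean(res["ctrl", ] < 0.05), 0.8)
  expect_lte(mean(res["diet", ] < 0.05), mean(res["ctrl", ] < 0.05) - 0.3)
})
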