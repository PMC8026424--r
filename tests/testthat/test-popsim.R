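test_that("population draws honour omega and the covariate model", {
  p <- test_params(omega = omega_matrix())  # omega = 0
  inds <- sample_population(p, c(60, 70, 85), seed = 4)
  typ <- apply_weight_covariates(p, c(60, 70, 85))
  expect_equal(inds$cl0_i, typ$cl0)
  expect_equal(inds$v1_i, typ$v1)
  expect_equal(inds$emax_i, rep(p$emax, 3))

  # determinism: bit-identical draws for a fixed seed
  pfull <- test_params()
  a <- sample_population(pfull, rep(70, 50), seed = 9)
  b <- sample_population(pfull, rep(70, 50), seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, sample_population(pfull, rep(70, 50), seed = 10)))

  # law of large numbers on the log-clearance variance
  pd <- test_params(omega = omega_matrix(var_cl = 0.09, var_v1 = 0.04,
                                         var_v2 = 0.25, var_emax = 0.01))
  big <- sample_population(pd, rep(70, 10000), seed = 5)
  v <- stats::var(log(big$cl0_i) - log(pd$cl0_pop))
  expect_lt(abs(v / 0.09 - 1), 0.05)

  expect_error(sample_population(p, numeric(0)), "non-empty")
  expect_error(sample_population(p, c(70, -1)), "positive")
})

test_that("simulated arms compose the per-subject machinery faithfully", {
  p0 <- test_params(omega = omega_matrix())
  reg <- regimen(8, "Q2W", 60, n_cycles = 1)
  arm <- simulate_arm(p0, reg, n = 1, weight_pool = rep(75, 3), seed = 2)
  # 8 mg/kg at 75 kg -> 600 mg per dose
  expect_equal(unique(arm$doses$amount_mg), 600)
  # composition identity with the single-subject solver
  ind <- individual_from_typical(p0, 75)
  direct <- solve_profile(ind, p0, dose_schedule(reg, 75),
                          unique(arm$profiles$time_h))
  expect_equal(arm$profiles$conc_ug_ml, direct$conc_ug_ml, tolerance = 1e-10)

  # same seed, different infusion duration: same subjects and parameters
  p <- test_params()
  pool <- withr::with_seed(1, stats::rlnorm(40, log(65), 0.2))
  a30 <- simulate_arm(p, regimen(8, "Q2W", 30, 1), 10, pool, seed = 6)
  a60 <- simulate_arm(p, regimen(8, "Q2W", 60, 1), 10, pool, seed = 6)
  expect_identical(a30$individuals, a60$individuals)
  expect_equal(unique(a60$doses$duration_h), 1)
  expect_equal(unique(a30$doses$duration_h), 0.5)

  expect_error(simulate_arm(p, reg, 10, rep(70, 5), seed = 1),
               "weight pool")
})

test_that("exposure metrics reproduce analytic identities", {
  # all-zero profile
  zero <- tibble::tibble(time_h = seq(0, 336, length.out = 300),
                         conc_ug_ml = 0)
  doses0 <- tibble::tibble(start_h = 0, amount_mg = 0, duration_h = 1)
  m <- exposure_metrics(zero, doses0, "first_dose", tau_h = 336)
  expect_equal(c(m$cmax, m$cmin, m$auc_tau), c(0, 0, 0))

  # one-compartment constant clearance: AUC_0-inf = Dose / CL
  ind <- list(cl0_i = 0.08, v1_i = 5, v2_i = 3, q_i = 0, emax_i = 0)
  dose <- tibble::tibble(start_h = 0, amount_mg = 400, duration_h = 1)
  tau <- 3000  # ~6 terminal half-lives: near-complete AUC
  tt <- seq(0, tau, length.out = 8000)
  prof <- closed_form_profile(ind, dose, tt)
  m1 <- exposure_metrics(prof, dose, "first_dose", tau_h = tau)
  expect_lt(abs(m1$auc_tau / (400 / 0.08) - 1), 0.005)

  # insufficient grid coverage errors
  expect_error(exposure_metrics(prof[seq(1, 8000, by = 100), ], dose,
                                "first_dose", tau_h = tau),
               "points")
})

test_that("30- vs 60-min infusions of the same subject are exposure-equivalent", {
  p <- test_params()
  ind <- individual_from_typical(p, 72)
  tau <- 336
  tt <- profile_grid(regimen(8, "Q2W", 60, 1))
  d30 <- tibble::tibble(start_h = 0, amount_mg = 576, duration_h = 0.5)
  d60 <- tibble::tibble(start_h = 0, amount_mg = 576, duration_h = 1)
  e30 <- exposure_metrics(solve_profile(ind, p, d30, sort(unique(c(tt, 0.5)))),
                          d30, "first_dose", tau_h = tau)
  e60 <- exposure_metrics(solve_profile(ind, p, d60, tt), d60, "first_dose",
                          tau_h = tau)
  expect_gte(e30$cmax, e60$cmax)
  expect_true(abs(e30$auc_tau / e60$auc_tau - 1) < 1e-3)
})

test_that("successive troughs stabilise below 1% at declared steady state", {
  p <- test_params()
  ind <- individual_from_typical(p, 70)
  reg <- regimen(8, "Q2W", 60, n_cycles = 15)
  doses <- dose_schedule(reg, 70)
  prof <- solve_profile(ind, p, doses, profile_grid(reg))
  m <- exposure_metrics(prof, doses, "steady_state", tau_h = 336)
  k <- m$interval_start_h / 336
  troughs <- stats::approx(prof$time_h, prof$conc_ug_ml,
                           xout = c(k, k + 1) * 336)$y
  expect_lt(abs(troughs[2] / troughs[1] - 1), 0.01)
  expect_gt(k, 1)  # steady state is never declared at the first interval
  # short horizons refuse to declare steady state
  reg2 <- regimen(8, "Q2W", 60, n_cycles = 2)
  prof2 <- solve_profile(ind, p, dose_schedule(reg2, 70), profile_grid(reg2))
  expect_error(exposure_metrics(prof2, dose_schedule(reg2, 70),
                                "steady_state", tau_h = 336),
               "steady state")
})

test_that("population percentile curves scale linearly with dose", {
  p <- test_params()
  pool <- withr::with_seed(3, stats::rlnorm(30, log(65), 0.2))
  tt <- seq(0, 336, length.out = 120)
  a1 <- simulate_arm(p, regimen(8, "Q2W", 60, 1), 12, pool, seed = 8,
                     times = tt)
  a2 <- simulate_arm(p, regimen(16, "Q2W", 60, 1), 12, pool, seed = 8,
                     times = tt)
  q1 <- tapply(a1$profiles$conc_ug_ml, a1$profiles$time_h,
               stats::quantile, probs = c(0.05, 0.5, 0.95))
  q2 <- tapply(a2$profiles$conc_ug_ml, a2$profiles$time_h,
               stats::quantile, probs = c(0.05, 0.5, 0.95))
  rel <- abs(unlist(q2) - 2 * unlist(q1)) / pmax(unlist(q2), 1e-9)
  expect_lt(max(rel[unlist(q2) > 1e-6]), 1e-6)
})

test_that("paired 30/60-min arms meet the equivalence bands at modest n", {
  p <- test_params()
  pool <- withr::with_seed(11, stats::rlnorm(80, log(65), sqrt(log(1.04))))
  a30 <- simulate_arm(p, regimen(8, "Q2W", 30, 1), 30, pool, seed = 3)
  a60 <- simulate_arm(p, regimen(8, "Q2W", 60, 1), 30, pool, seed = 3)
  e30 <- arm_exposure(a30)
  e60 <- arm_exposure(a60)
  cmp <- exposure_comparison(e30, e60)
  expect_gt(cmp$ratios$auc_tau_gmr, 0.995)
  expect_lt(cmp$ratios$auc_tau_gmr, 1.005)
  expect_gte(cmp$ratios$cmax_gmr, 0.95)
  expect_lte(cmp$ratios$cmax_gmr, 1.10)
  expect_true(all(e30$cmax >= e60$cmax))
  expect_setequal(cmp$by_arm$metric, c("auc_tau", "cmax", "cmin"))
})
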