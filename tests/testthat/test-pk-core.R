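test_that("the two closed-form evaluations agree to near machine precision", {
  withr::local_seed(101)
  for (i in 1:12) {
    ind <- random_const_cl_individual()
    dose <- tibble::tibble(start_h = 0, amount_mg = stats::runif(1, 200, 1000),
                           duration_h = stats::runif(1, 0.5, 1.5))
    tt <- seq(0, 500, length.out = 80)
    hy <- closed_form_profile(ind, dose, tt, method = "hybrid")
    ex <- closed_form_profile(ind, dose, tt, method = "expm")
    scale <- max(hy$conc_ug_ml)
    expect_lt(max(abs(hy$conc_ug_ml - ex$conc_ug_ml)) / scale, 1e-10)
  }
})

test_that("the matrix-exponential route matches an external expm oracle", {
  skip_if_not_installed("Matrix")
  withr::local_seed(7)
  ind <- random_const_cl_individual()
  A <- matrix(c(-(ind$cl0_i + ind$q_i) / ind$v1_i, ind$q_i / ind$v1_i,
                ind$q_i / ind$v2_i, -ind$q_i / ind$v2_i), nrow = 2)
  x <- c(40, 13)
  for (dt in c(0.3, 5, 60)) {
    ours <- ramupk:::.expm_step(A, x, c(0, 0), dt)
    ref <- as.matrix(Matrix::expm(A * dt)) %*% x
    expect_equal(as.vector(ours), as.vector(ref), tolerance = 1e-10)
  }
})

test_that("closed form reduces to the one-compartment solution when Q = 0", {
  ind <- list(cl0_i = 0.05, v1_i = 6, v2_i = 3, q_i = 0, emax_i = 0)
  dose <- tibble::tibble(start_h = 0, amount_mg = 300, duration_h = 2)
  tt <- c(0, 0.5, 1, 2, 5, 24, 120)
  got <- closed_form_profile(ind, dose, tt)
  rate <- 300 / 2
  k <- 0.05 / 6
  manual <- ifelse(tt <= 0, 0,
                   ifelse(tt <= 2, rate / 0.05 * (1 - exp(-k * tt)),
                          rate / 0.05 * (1 - exp(-k * 2)) *
                            exp(-k * (tt - 2)))) / 1  # conc = A1/V1 = C
  expect_equal(got$conc_ug_ml, manual, tolerance = 1e-12)
  expect_equal(got$conc_ug_ml[1], 0)
})

test_that("closed form refuses time-varying clearance", {
  ind <- list(cl0_i = 0.05, v1_i = 6, v2_i = 3, q_i = 0.01, emax_i = -0.1)
  dose <- tibble::tibble(start_h = 0, amount_mg = 300, duration_h = 1)
  expect_error(closed_form_profile(ind, dose, c(0, 1)), "constant clearance")
})

test_that("ODE solution matches the closed form under constant clearance", {
  withr::local_seed(2024)
  model <- const_cl_model()
  for (i in 1:10) {
    ind <- random_const_cl_individual()
    dose <- tibble::tibble(start_h = 0, amount_mg = stats::runif(1, 200, 900),
                           duration_h = stats::runif(1, 0.5, 1.5))
    tt <- seq(0, 336, length.out = 100)
    num <- solve_profile(ind, model, dose, tt)
    ana <- closed_form_profile(ind, dose, tt)
    expect_lt(max(abs(num$conc_ug_ml - ana$conc_ug_ml)) /
                max(ana$conc_ug_ml), 1e-6)
  }
})

test_that("profiles superpose and scale linearly in dose", {
  model <- const_cl_model()
  ind <- list(cl0_i = 0.02, v1_i = 5, v2_i = 3, q_i = 0.02, emax_i = 0)
  tt <- seq(0, 700, length.out = 150)
  d1 <- tibble::tibble(start_h = 0, amount_mg = 500, duration_h = 1)
  d2 <- tibble::tibble(start_h = 336, amount_mg = 700, duration_h = 0.5)
  both <- solve_profile(ind, model, dplyr::bind_rows(d1, d2), tt)
  sum_of_one <- solve_profile(ind, model, d1, tt)$conc_ug_ml +
    solve_profile(ind, model, d2, tt)$conc_ug_ml
  expect_lt(max(abs(both$conc_ug_ml - sum_of_one)) / max(sum_of_one), 1e-6)

  # linearity holds with time-varying clearance too
  tv <- test_params()
  ind_tv <- individual_from_typical(tv, 70)
  base <- solve_profile(ind_tv, tv, dplyr::bind_rows(d1, d2), tt)
  dbl <- solve_profile(ind_tv, tv,
                       dplyr::mutate(dplyr::bind_rows(d1, d2),
                                     amount_mg = 2 * amount_mg), tt)
  expect_lt(max(abs(dbl$conc_ug_ml - 2 * base$conc_ug_ml)) /
              max(dbl$conc_ug_ml), 1e-6)
})

test_that("eliminated mass equals the administered dose (constant CL)", {
  # near-bolus input, fast-ish constants so the tail truncation is tiny
  ind <- list(cl0_i = 0.1, v1_i = 5, v2_i = 5, q_i = 0.05, emax_i = 0)
  dose <- tibble::tibble(start_h = 0, amount_mg = 400, duration_h = 1 / 60)
  tt <- sort(unique(c(seq(0, 5, length.out = 2000),
                      seq(5, 4000, length.out = 20000))))
  prof <- closed_form_profile(ind, dose, tt)
  integrand <- ind$cl0_i * prof$conc_ug_ml
  eliminated <- sum(diff(tt) * (utils::head(integrand, -1) +
                                  utils::tail(integrand, -1)) / 2)
  expect_lt(abs(eliminated / 400 - 1), 0.005)
})

test_that("degenerate dosing inputs are rejected, empty dosing is zero", {
  model <- const_cl_model()
  ind <- list(cl0_i = 0.02, v1_i = 5, v2_i = 3, q_i = 0.02, emax_i = 0)
  tt <- c(0, 10, 20)
  zero <- solve_profile(ind, model,
                        tibble::tibble(start_h = numeric(), amount_mg = numeric(),
                                       duration_h = numeric()), tt)
  expect_equal(zero$conc_ug_ml, c(0, 0, 0))
  expect_error(solve_profile(ind, model,
                             tibble::tibble(start_h = c(10, 0),
                                            amount_mg = 1, duration_h = 1), tt),
               "sorted")
  expect_error(solve_profile(ind, model,
                             tibble::tibble(start_h = c(0, 0.25),
                                            amount_mg = 1, duration_h = 1), tt),
               "overlap")
  expect_error(solve_profile(ind, model,
                             tibble::tibble(start_h = 0, amount_mg = 1,
                                            duration_h = 0), tt),
               "bolus")
  expect_error(solve_profile(ind, model,
                             tibble::tibble(start_h = 0, amount_mg = 1,
                                            duration_h = 1), c(-1, 2)),
               "non-negative")
})

test_that("the semi-analytic propagator tracks the adaptive solver", {
  p <- test_params()
  ind <- individual_from_typical(p, 78)
  reg <- regimen(8, "Q2W", 60, n_cycles = 3)
  doses <- dose_schedule(reg, 78)
  tt <- c(0.5, 1, 2, 6, 12, 24, 72, 168, 335, 340, 420, 671, 900, 1007)
  a <- solve_profile(ind, p, doses, tt)
  b <- ramupk:::.profile_fast(as.list(ind), p, doses, tt, substeps = 4L)
  expect_lt(max(abs(a$conc_ug_ml - b$conc_ug_ml) / pmax(a$conc_ug_ml, 1e-9)),
            2e-4)
})
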