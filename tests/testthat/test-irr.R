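test_that("percentages round half away from zero to one decimal", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(2.45, 1), 2.5)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(7.899, 1), 7.9)
  # every printed per-study incidence cell reproduces from its n/N counts
  n <- c(6, 45, 51, 46, 41, 17, 15, 18, 4, 11, 254)
  N <- c(236, 327, 626, 528, 317, 197, 323, 258, 161, 243, 3216)
  printed <- c(2.5, 13.8, 8.1, 8.7, 12.9, 8.6, 4.6, 7.0, 2.5, 4.5, 7.9)
  expect_equal(round_half_up(100 * n / N, 1), printed)
  # quartile-table cells: any-grade and grade >= 3 and category rows
  n3 <- c(87, 65, 40, 60, 2, 254, 5, 5, 5, 2, 17, 40, 174, 86)
  N3 <- c(799, 803, 797, 794, 23, 3216, 799, 803, 797, 794, 3216, 3216,
          3216, 3216)
  printed3 <- c(10.9, 8.1, 5.0, 7.6, 8.7, 7.9, 0.6, 0.6, 0.6, 0.3, 0.5,
                1.2, 5.4, 2.7)
  expect_equal(round_half_up(100 * n3 / N3, 1), printed3)
})

test_that("infusion rates follow the earliest-IRR / first-dose rule", {
  rec <- tibble::tibble(
    irr_flag = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    dose_mg = c(800, 900, 600, 500, 700),
    duration_min = c(60, 55, 60, NA, 0),
    irr_day_dose_mg = c(910, 950, NA, NA, 700),
    irr_day_duration_min = c(5, 5, NA, NA, 0)
  )
  out <- compute_infusion_rate(rec)
  # the two data-entry outliers the pooled analysis retained
  expect_equal(out$infusion_rate_mg_min[1:2], c(182, 190))
  expect_equal(out$infusion_rate_mg_min[3], 10)
  expect_true(is.na(out$infusion_rate_mg_min[4]))
  expect_equal(out$rate_missing_reason[4], "missing infusion duration")
  expect_equal(out$rate_missing_reason[5], "non-positive infusion duration")
  # without IRR-day columns the first dose is used throughout
  out2 <- compute_infusion_rate(rec[, c("irr_flag", "dose_mg", "duration_min")])
  expect_equal(out2$infusion_rate_mg_min[2], 900 / 55)
})

test_that("the 60-minute sensitivity rate ignores recorded durations", {
  rec <- tibble::tibble(irr_flag = c(FALSE, FALSE, FALSE),
                        dose_mg = c(600, 910, 910),
                        duration_min = c(30, 90, NA))
  out <- sensitivity_rate(rec)
  expect_equal(out$infusion_rate_mg_min, c(10, 910 / 60, 910 / 60))
  expect_equal(out$infusion_rate_mg_min[2], 15.1667, tolerance = 1e-4)
  # identical output whatever the recorded duration was
  rec2 <- dplyr::mutate(rec, duration_min = c(90, 30, 5))
  expect_equal(sensitivity_rate(rec2)$infusion_rate_mg_min,
               out$infusion_rate_mg_min)
})

test_that("quartile grouping uses lower empirical quantiles with ties down", {
  rec <- tibble::tibble(infusion_rate_mg_min = as.numeric(1:8))
  g <- quartile_groups(rec)
  expect_equal(as.character(g$rate_quartile),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  # a value equal to the boundary falls in the lower group
  rec2 <- tibble::tibble(infusion_rate_mg_min = c(1, 2, 2, 3, 5, 6, 7, 9))
  g2 <- quartile_groups(rec2)
  b <- attr(g2, "boundaries")
  at_boundary <- which(rec2$infusion_rate_mg_min == b[["p25"]])
  expect_true(all(g2$rate_quartile[at_boundary] %in% c("Q1")))

  # near-balanced group sizes on tie-free data
  withr::local_seed(31)
  big <- tibble::tibble(infusion_rate_mg_min = stats::rlnorm(3193, 2.2, 0.3))
  gb <- quartile_groups(big)
  sizes <- table(gb$rate_quartile)[c("Q1", "Q2", "Q3", "Q4")]
  expect_true(all(abs(sizes - 3193 / 4) <= 2))

  # missing rates form their own column
  mix <- tibble::tibble(infusion_rate_mg_min = c(stats::rlnorm(3193, 2.2, 0.3),
                                                 rep(NA_real_, 23)))
  gm <- quartile_groups(mix)
  expect_equal(sum(gm$rate_quartile == "Missing"), 23)
  expect_equal(nrow(gm), 3216)

  # permutation invariance and idempotence
  perm <- big[sample.int(nrow(big)), ]
  gp <- quartile_groups(perm)
  expect_equal(
    dplyr::arrange(gp, infusion_rate_mg_min)$rate_quartile,
    dplyr::arrange(gb, infusion_rate_mg_min)$rate_quartile
  )
  expect_equal(quartile_groups(gb)$rate_quartile, gb$rate_quartile)

  expect_error(quartile_groups(tibble::tibble(infusion_rate_mg_min =
                                                c(NA_real_, NA_real_, NA_real_, NA_real_))),
               "non-missing")
  expect_error(quartile_groups(tibble::tibble(infusion_rate_mg_min = c(1, 2, 3))),
               "at least 4")
})

test_that("incidence tables reproduce printed pooled and quartile cells", {
  tab <- incidence_table(count_records(254, 3216, grade3_events = 17),
                         group_col = "grp")
  any_tot <- tab[tab$group == "Total" & tab$outcome == "any_grade", ]
  expect_equal(any_tot$n, 254)
  expect_equal(any_tot$pct, 7.9)
  g3 <- tab[tab$group == "Total" & tab$outcome == "grade_ge3", ]
  expect_equal(g3$pct, 0.5)

  q1 <- incidence_table(count_records(87, 799), group_col = "grp")
  expect_equal(q1$pct[q1$outcome == "any_grade" & q1$group == "Total"], 10.9)

  regard <- incidence_table(count_records(6, 236), group_col = "grp")
  expect_equal(regard$pct[regard$outcome == "any_grade" &
                            regard$group == "Total"], 2.5)

  none <- incidence_table(count_records(0, 500), group_col = "grp")
  expect_equal(none$pct[none$outcome == "any_grade" & none$group == "Total"],
               0)

  # category rows are tabulated per group when present
  rec <- count_records(10, 100)
  rec$irr_category <- c(rep("hypersensitivity", 10), rep(NA, 90))
  tabc <- incidence_table(rec, group_col = "grp")
  hc <- tabc[tabc$category == "hypersensitivity" & tabc$outcome == "any_grade" &
               tabc$group == "Total", ]
  expect_equal(hc$n, 10)
  expect_equal(hc$pct, 10.0)
})

test_that("logistic model reproduces the 2x2 cross-product odds ratio", {
  # a = 20 exposed cases, b = 80 exposed non-cases, c = 10, d = 90
  rec <- tibble::tibble(
    irr_flag = c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 10), rep(FALSE, 90)),
    premedication = c(rep(TRUE, 100), rep(FALSE, 100)),
    infusion_rate_mg_min = 10,
    age_ge_65 = FALSE, sex = "male", region_asia = FALSE,
    chemotherapy = FALSE, regimen = "8Q2W"
  )
  fit <- logistic_model(rec)
  td <- tidy(fit)
  expect_equal(td$or[td$term == "premedication"], (20 * 90) / (80 * 10),
               tolerance = 1e-6)
  # constant covariates are dropped rather than crashing the contrasts
  expect_false(".rate" %in% td$term)
})

test_that("intercept-only fit returns the observed proportion", {
  rec <- tibble::tibble(
    irr_flag = c(rep(TRUE, 13), rep(FALSE, 87)),
    premedication = FALSE, infusion_rate_mg_min = 10,
    age_ge_65 = FALSE, sex = "male", region_asia = FALSE,
    chemotherapy = FALSE, regimen = "8Q2W"
  )
  fit <- logistic_model(rec)
  expect_equal(unique(round(stats::fitted(fit$fit), 10)), 0.13)
  expect_equal(glance(fit)$n_events, 13)
})

test_that("a covariate independent of outcome gives a null odds ratio", {
  withr::local_seed(55)
  n <- 1e5
  rec <- tibble::tibble(
    irr_flag = stats::runif(n) < 0.08,
    premedication = stats::runif(n) < 0.5,
    infusion_rate_mg_min = stats::rlnorm(n, 2.2, 0.3),
    age_ge_65 = stats::runif(n) < 0.4,
    sex = sample(c("male", "female"), n, TRUE),
    region_asia = FALSE, chemotherapy = FALSE, regimen = "8Q2W"
  )
  td <- tidy(logistic_model(rec))
  expect_gt(td$or[td$term == "premedication"], 0.95)
  expect_lt(td$or[td$term == "premedication"], 1.05)
})

test_that("perfect separation is reported as a failed fit, not a crash", {
  rec <- tibble::tibble(
    irr_flag = c(rep(TRUE, 30), rep(FALSE, 170)),
    premedication = c(rep(TRUE, 30), rep(FALSE, 170)),
    infusion_rate_mg_min = 10,
    age_ge_65 = FALSE, sex = "male", region_asia = FALSE,
    chemotherapy = FALSE, regimen = "8Q2W"
  )
  fit <- suppressWarnings(logistic_model(rec))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation")
})

test_that("records with missing rates are excluded and counted", {
  spec <- cohort_spec(n_patients = 400, prop_missing_duration = 0.05,
                      seed = 14)
  coh <- compute_infusion_rate(generate_irr_cohort(spec))
  fit <- logistic_model(coh)
  expect_equal(fit$n_excluded_missing_rate, sum(is.na(coh$infusion_rate_mg_min)))
  expect_equal(fit$n_used + fit$n_excluded_missing_rate, 400)
})

test_that("fitted intervals are calibrated on average across factors", {
  truth <- ramucirumab_irr_odds_ratios()
  reps <- 60
  cover <- matrix(NA, reps, nrow(truth))
  for (r in seq_len(reps)) {
    coh <- generate_irr_cohort(cohort_spec(n_patients = 3216, seed = 5000 + r))
    td <- tidy(logistic_model(quartile_groups(compute_infusion_rate(coh))))
    td$term[td$term == ".rate"] <- "rate"
    m <- match(truth$term, td$term)
    cover[r, ] <- truth$or >= td$ci_lo[m] & truth$or <= td$ci_hi[m]
  }
  # mean coverage pooled over the ten factors concentrates near 95%
  expect_gte(mean(cover), 0.93)
})
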