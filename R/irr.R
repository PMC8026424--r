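#' Round half away from zero
#'
#' Table percentages in clinical reporting are conventionally rounded half-up
#' (SAS-style), not to even as `round()` does.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive per-patient infusion rates
#'
#' The analysis rate is total dose / infusion duration (mg/min) at the
#' rule-selected administration: the administration on the day of the
#' earliest immediate infusion-related reaction for patients with at least
#' one immediate IRR, and the first ramucirumab dose for patients without.
#' Records whose rule-selected duration is missing or non-positive get a
#' missing rate and a reason.
#'
#' @param records Cohort tibble with `irr_flag`, first-dose columns
#'   `dose_mg` and `duration_min`, and (for IRR patients) the earliest-IRR-day
#'   columns `irr_day_dose_mg`, `irr_day_duration_min`. If the IRR-day
#'   columns are absent the first-dose administration is used throughout.
#' @return `records` with `infusion_rate_mg_min` and `rate_missing_reason`
#'   columns added.
#' @export
compute_infusion_rate <- function(records) {
  stopifnot(all(c("irr_flag", "dose_mg", "duration_min") %in% names(records)))
  has_irr_cols <- all(c("irr_day_dose_mg", "irr_day_duration_min") %in%
                        names(records))
  use_irr <- records$irr_flag & has_irr_cols
  dose <- ifelse(use_irr, records[["irr_day_dose_mg"]] %||% NA_real_,
                 records$dose_mg)
  dur <- ifelse(use_irr, records[["irr_day_duration_min"]] %||% NA_real_,
                records$duration_min)
  bad_dur <- is.na(dur) | dur <= 0
  bad_dose <- is.na(dose)
  rate <- ifelse(bad_dur | bad_dose, NA_real_, dose / dur)
  reason <- dplyr::case_when(
    bad_dose ~ "missing dose",
    is.na(dur) ~ "missing infusion duration",
    dur <= 0 ~ "non-positive infusion duration",
    .default = NA_character_
  )
  dplyr::mutate(tibble::as_tibble(records),
                infusion_rate_mg_min = rate,
                rate_missing_reason = reason)
}

#' Sensitivity infusion rate assuming a standard 60-minute infusion
#'
#' Because observed infusion durations are themselves affected by IRR
#' management (interrupted infusions run long), a sensitivity analysis
#' recomputes every rate as total dose / 60 min, ignoring the recorded
#' duration entirely.
#'
#' @param records Cohort tibble with `dose_mg` (and optionally
#'   `irr_day_dose_mg` + `irr_flag` for the rule-selected dose).
#' @return `records` with `infusion_rate_mg_min` (= dose/60) and
#'   `rate_missing_reason` columns.
#' @export
sensitivity_rate <- function(records) {
  stopifnot("dose_mg" %in% names(records))
  has_irr_cols <- all(c("irr_flag", "irr_day_dose_mg") %in% names(records))
  dose <- if (has_irr_cols) {
    ifelse(records$irr_flag, records$irr_day_dose_mg, records$dose_mg)
  } else {
    records$dose_mg
  }
  dplyr::mutate(tibble::as_tibble(records),
                infusion_rate_mg_min = dose / 60,
                rate_missing_reason = ifelse(is.na(dose), "missing dose",
                                             NA_character_))
}

#' Assign infusion-rate quartile groups
#'
#' Non-missing rates are split at their empirical 25th/50th/75th percentiles
#' (lower/type-1 empirical-CDF quantiles). A rate equal to a boundary goes to
#' the lower quartile; missing rates form their own group; extreme rates are
#' retained in Q4 rather than trimmed. The operation is permutation-invariant
#' and idempotent.
#'
#' @param records Tibble with an `infusion_rate_mg_min` column (see
#'   [compute_infusion_rate()]).
#' @param rate_col Name of the rate column.
#' @return `records` with a `rate_quartile` factor (`Q1`..`Q4`, `Missing`);
#'   quartile boundaries are attached as attribute `"boundaries"`.
#' @export
quartile_groups <- function(records, rate_col = "infusion_rate_mg_min") {
  rates <- records[[rate_col]]
  if (is.null(rates)) stop("column `", rate_col, "` not found", call. = FALSE)
  ok <- !is.na(rates)
  if (sum(ok) < 4) {
    stop("need at least 4 non-missing rates to form quartiles", call. = FALSE)
  }
  qs <- stats::quantile(rates[ok], probs = c(0.25, 0.5, 0.75), type = 1,
                        names = FALSE)
  grp <- rep(NA_character_, length(rates))
  grp[ok] <- paste0("Q", 1 + (rates[ok] > qs[1]) + (rates[ok] > qs[2]) +
                      (rates[ok] > qs[3]))
  grp[!ok] <- "Missing"
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    rate_quartile = factor(grp, levels = c("Q1", "Q2", "Q3", "Q4", "Missing"))
  )
  attr(out, "boundaries") <- stats::setNames(qs, c("p25", "p50", "p75"))
  out
}

#' Incidence of immediate IRRs by group
#'
#' Tabulates patients with at least one event per group (quartile groups by
#' default), for any-grade and grade >= 3 outcomes and, when an
#' `irr_category` column is present, per category. Percentages are
#' 100 * n / N rounded half-up to one decimal. A `Total` row pools all
#' groups.
#'
#' @param records Tibble with `irr_flag`, `irr_grade_ge3`, a grouping column
#'   and optionally `irr_category`.
#' @param group_col Name of the grouping column (default `"rate_quartile"`).
#' @return Long tibble: `group`, `N`, `outcome`, `category`, `n`, `pct`.
#' @export
incidence_table <- function(records, group_col = "rate_quartile") {
  stopifnot(group_col %in% names(records), "irr_flag" %in% names(records))
  records <- tibble::as_tibble(records)
  if (!"irr_grade_ge3" %in% names(records)) records$irr_grade_ge3 <- FALSE
  grp <- records[[group_col]]
  if (!is.factor(grp)) grp <- factor(grp)

  cell <- function(sel, flag, label, category, total_n) {
    n <- sum(flag[sel], na.rm = TRUE)
    tibble::tibble(outcome = label, category = category, n = n,
                   pct = round_half_up(100 * n / total_n, 1))
  }
  one_group <- function(sel, gname) {
    N <- sum(sel)
    rows <- dplyr::bind_rows(
      cell(sel, records$irr_flag, "any_grade", "all", N),
      cell(sel, records$irr_grade_ge3, "grade_ge3", "all", N)
    )
    if ("irr_category" %in% names(records)) {
      cats <- sort(unique(stats::na.omit(records$irr_category)))
      for (ct in cats) {
        in_cat <- !is.na(records$irr_category) & records$irr_category == ct
        rows <- dplyr::bind_rows(
          rows,
          cell(sel, records$irr_flag & in_cat, "any_grade", ct, N),
          cell(sel, records$irr_grade_ge3 & in_cat, "grade_ge3", ct, N)
        )
      }
    }
    dplyr::mutate(rows, group = gname, N = N, .before = 1)
  }
  out <- dplyr::bind_rows(
    purrr::map(levels(grp), function(g) one_group(!is.na(grp) & grp == g, g)),
    one_group(rep(TRUE, nrow(records)), "Total")
  )
  out[out$N > 0 | out$group == "Total", ]
}

#' Multivariate logistic model of immediate-IRR risk
#'
#' Fits the pooled maximum-likelihood logistic regression of immediate-IRR
#' occurrence on infusion rate (continuous, per 1 mg/min) adjusted for age
#' (>= 65 vs < 65), sex (female vs male), region (Asia vs rest of world),
#' premedication (yes vs no), chemotherapy (yes vs no) and dosing regimen
#' (reference 8 mg/kg Q2W). Baseline body weight is deliberately not a
#' covariate: it is strongly correlated with infusion rate under weight-based
#' dosing. Records with a missing rate are excluded and counted. Odds ratios
#' use Wald 95% intervals, `exp(beta +/- 1.96 SE)`.
#'
#' @param records Cohort tibble with `irr_flag`, the covariate columns
#'   (`age_ge_65`, `sex`, `region_asia`, `premedication`, `chemotherapy`,
#'   `regimen`) and a rate column.
#' @param rate_col Name of the continuous rate column.
#' @param outcome Outcome column (default `irr_flag`).
#' @return An `irr_fit` object wrapping the `glm`; see [tidy.irr_fit()]. A
#'   fit showing signs of separation (unbounded coefficients / huge standard
#'   errors) is returned with `converged = FALSE` and a diagnostic rather
#'   than raising.
#' @export
logistic_model <- function(records, rate_col = "infusion_rate_mg_min",
                           outcome = "irr_flag") {
  covars <- c("age_ge_65", "sex", "region_asia", "premedication",
              "chemotherapy", "regimen")
  need <- c(outcome, rate_col, covars)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(records)
  n_total <- nrow(d)
  d <- d[!is.na(d[[rate_col]]), ]
  n_excluded <- n_total - nrow(d)

  d$.y <- as.integer(d[[outcome]])
  d$.rate <- d[[rate_col]]
  d$sex <- factor(d$sex)
  if ("male" %in% levels(d$sex)) d$sex <- stats::relevel(d$sex, ref = "male")
  d$regimen <- factor(d$regimen)
  if ("8Q2W" %in% levels(d$regimen)) {
    d$regimen <- stats::relevel(d$regimen, ref = "8Q2W")
  }
  for (v in c("age_ge_65", "region_asia", "premedication", "chemotherapy")) {
    d[[v]] <- as.integer(d[[v]])
  }
  # covariates constant in the data carry no contrast; drop them rather
  # than let the factor machinery error
  terms <- c(".rate", "age_ge_65", "sex", "region_asia", "premedication",
             "chemotherapy", "regimen")
  dropped <- terms[vapply(terms, function(v) length(unique(d[[v]])) < 2,
                          logical(1))]
  kept <- setdiff(terms, dropped)
  rhs <- if (length(kept)) paste(kept, collapse = " + ") else "1"
  fit <- stats::glm(
    stats::as.formula(paste(".y ~", rhs)),
    family = stats::binomial(), data = d
  )
  co <- summary(fit)$coefficients
  separated <- !fit$converged ||
    any(abs(co[, "Estimate"]) > 15) || any(co[, "Std. Error"] > 100)
  structure(
    list(fit = fit, n_used = nrow(d), n_excluded_missing_rate = n_excluded,
         dropped_covariates = dropped,
         converged = !separated,
         diagnostic = if (separated) {
           "possible separation: unbounded coefficient or huge standard error"
         } else {
           NA_character_
         }),
    class = "irr_fit"
  )
}

irr_term_labels <- function(terms) {
  lab <- list(
    ".rate" = c("Infusion rate", "1-unit increase, mg/min"),
    "age_ge_65" = c("Age", ">= 65 vs < 65 years"),
    "sexfemale" = c("Sex", "Female vs male"),
    "region_asia" = c("Region", "Asia vs rest of the world"),
    "premedication" = c("Premedication", "Yes vs no"),
    "chemotherapy" = c("Chemotherapy", "Yes vs no"),
    "regimen10Q3W" = c("Dosing regimen", "10 mg/kg Q3W vs 8 mg/kg Q2W"),
    "regimen12Q2W" = c("Dosing regimen", "12 mg/kg Q2W vs 8 mg/kg Q2W"),
    "regimen6QW" = c("Dosing regimen", "6 mg/kg QW vs 8 mg/kg Q2W"),
    "regimen8D1D8Q3W" = c("Dosing regimen", "8 mg/kg D1D8 Q3W vs 8 mg/kg Q2W")
  )
  t(vapply(terms, function(tm) lab[[tm]] %||% c(tm, tm), character(2)))
}

#' Tidy an IRR logistic fit into Table-4 shape
#'
#' @param x An `irr_fit`.
#' @param ... Unused.
#' @return Tibble: `factor`, `comparison`, `term`, `or`, `ci_lo`, `ci_hi`,
#'   `p_value` (intercept omitted).
#' @export
tidy.irr_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  labs <- irr_term_labels(rownames(co))
  tibble::tibble(
    factor = labs[, 1],
    comparison = labs[, 2],
    term = rownames(co),
    or = exp(co[, "Estimate"]),
    ci_lo = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
    ci_hi = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"]
  )
}

#' One-row summary of an IRR logistic fit
#'
#' @param x An `irr_fit`.
#' @param ... Unused.
#' @return Tibble: `n_used`, `n_excluded_missing_rate`, `n_events`,
#'   `converged`, `deviance`, `aic`.
#' @export
glance.irr_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used,
    n_excluded_missing_rate = x$n_excluded_missing_rate,
    n_events = sum(x$fit$y),
    converged = x$converged,
    deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}

#' @export
print.irr_fit <- function(x, ...) {
  cat(sprintf("<irr_fit> n = %d (%d excluded, missing rate), events = %d\n",
              x$n_used, x$n_excluded_missing_rate, sum(x$fit$y)))
  if (!x$converged) cat("  WARNING:", x$diagnostic, "\n")
  print(tidy.irr_fit(x))
  invisible(x)
}

#' Bar chart of IRR incidence by infusion-rate quartile
#'
#' @param tab Output of [incidence_table()].
#' @param outcome Which outcome row to plot.
#' @return A ggplot object.
#' @export
plot_incidence <- function(tab, outcome = "any_grade") {
  d <- tab[tab$outcome == outcome & tab$category == "all" &
             tab$group != "Total", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n, .data$N)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Infusion-rate group", y = "Patients with >= 1 event (%)",
                  title = paste("Immediate IRR incidence,", outcome))
}
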