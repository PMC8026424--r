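nonmem_cols <- c("ID", "TIME", "AMT", "RATE", "DV", "MDV", "EVID", "WT")

#' Read a NONMEM-dialect PK dataset
#'
#' Comma-delimited with a header; `"."` or an empty field means missing.
#' Mandatory columns are `ID, TIME, AMT, RATE, DV, MDV, EVID, WT`. Row-level
#' invariants (dosing rows `EVID = 1` must carry `AMT > 0` and no `DV`;
#' observation rows must carry no `AMT`; `TIME` non-decreasing within `ID`)
#' are checked and offending rows reported in the attached validation report.
#'
#' @param path CSV file path.
#' @return Tibble of typed records with attribute `"validation"` (tibble of
#'   flagged rows and reasons).
#' @export
read_nonmem_dataset <- function(path) {
  d <- readr::read_csv(path, na = c(".", "", "NA"), show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double()))
  missing_cols <- setdiff(nonmem_cols, names(d))
  if (length(missing_cols)) {
    stop("dataset is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- d[nonmem_cols]
  d$ID <- as.integer(d$ID)
  d$MDV <- as.integer(d$MDV)
  d$EVID <- as.integer(d$EVID)

  flags <- list()
  bad_dose <- d$EVID == 1 & (is.na(d$AMT) | d$AMT <= 0 | !is.na(d$DV))
  if (any(bad_dose)) {
    flags$dose <- tibble::tibble(row = which(bad_dose),
                                 reason = "dosing row without AMT > 0 or with DV")
  }
  bad_obs <- d$EVID == 0 & !is.na(d$AMT)
  if (any(bad_obs)) {
    flags$obs <- tibble::tibble(row = which(bad_obs),
                                reason = "observation row carries AMT")
  }
  unsorted <- unlist(lapply(split(seq_len(nrow(d)), d$ID), function(ix) {
    ix[-1][diff(d$TIME[ix]) < 0]
  }))
  if (length(unsorted)) {
    flags$time <- tibble::tibble(row = as.integer(unsorted),
                                 reason = "TIME decreases within ID")
  }
  report <- dplyr::bind_rows(flags)
  if (nrow(report)) {
    warning(nrow(report), " row(s) violate dataset invariants; see attr(x, \"validation\")",
            call. = FALSE)
  }
  attr(d, "validation") <- report
  d
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", vapply(x, function(v) {
    if (is.na(v)) "." else format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1)))
}

#' Write a NONMEM-dialect PK dataset
#'
#' Missing fields are written as `"."`; numeric fields are serialized with 6
#' significant digits so that write -> read -> write round-trips
#' byte-for-byte on canonical files.
#'
#' @param d Dataset tibble (see [read_nonmem_dataset()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nonmem_dataset <- function(d, path) {
  stopifnot(all(nonmem_cols %in% names(d)))
  out <- d[nonmem_cols]
  txt <- vapply(nonmem_cols, function(cn) fmt_num(as.numeric(out[[cn]])),
                FUN.VALUE = character(nrow(out)))
  if (nrow(out) == 1L) txt <- matrix(txt, nrow = 1,
                                     dimnames = list(NULL, nonmem_cols))
  lines <- c(paste(nonmem_cols, collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read population-PK parameters from a YAML config
#'
#' Keys follow the [poppk_parameters()] arguments (`t50_days` etc.); the
#' omega matrix is given by its lower-triangular entries `omega_var_cl`,
#' `omega_var_v1`, `omega_var_v2`, `omega_var_emax`, `omega_cov_cl_v1`,
#' `omega_cov_cl_emax`.
#'
#' @param path YAML file path (or a pre-parsed list).
#' @return A `poppk_parameters` object.
#' @export
read_poppk_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  om <- omega_matrix(
    var_cl = cfg$omega_var_cl %||% 0, var_v1 = cfg$omega_var_v1 %||% 0,
    var_v2 = cfg$omega_var_v2 %||% 0, var_emax = cfg$omega_var_emax %||% 0,
    cov_cl_v1 = cfg$omega_cov_cl_v1 %||% 0,
    cov_cl_emax = cfg$omega_cov_cl_emax %||% 0
  )
  poppk_parameters(
    cl0_pop = cfg$cl0_pop, v1_pop = cfg$v1_pop, q = cfg$q,
    v2_pop = cfg$v2_pop, emax = cfg$emax %||% 0,
    t50_days = cfg$t50_days %||% 27, gamma = cfg$gamma %||% 2,
    theta_wt_cl = cfg$theta_wt_cl %||% 0.75,
    theta_wt_v1 = cfg$theta_wt_v1 %||% 1,
    wt_ref = cfg$wt_ref %||% 70, omega = om,
    sigma_add = cfg$sigma_add %||% 0, sigma_prop = cfg$sigma_prop %||% 0
  )
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    stop("config must list at least one stage", call. = FALSE)
  }
  known <- c("generate", "irr", "simulate", "expose", "vpc")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  if (any(c("simulate", "expose", "vpc") %in% cfg$stages) &&
      (is.null(cfg$model) || is.null(cfg$scenario))) {
    stop("PK stages need `model` and `scenario` blocks", call. = FALSE)
  }
  if ("irr" %in% cfg$stages && !"generate" %in% cfg$stages &&
      is.null(cfg$analysis$cohort_csv)) {
    stop("irr stage needs a cohort: run the generate stage or set analysis$cohort_csv",
         call. = FALSE)
  }
  if ("expose" %in% cfg$stages && !"simulate" %in% cfg$stages) {
    stop("expose stage needs the simulate stage in the same run", call. = FALSE)
  }
  invisible(cfg)
}

scenario_regimen <- function(sc, duration) {
  regimen(dose_per_kg = sc$dose_per_kg, schedule = sc$schedule,
          infusion_duration_min = duration,
          n_cycles = sc$n_cycles %||% 1)
}

write_with_sidecar <- function(df, path, cfg_hash, seed) {
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = seed,
         package_version = as.character(utils::packageVersion("ramupk")),
         rows = nrow(df)),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  path
}

#' Run the configured pipeline end to end
#'
#' Executes the requested stages in order — `generate` (synthetic IRR
#' cohort), `irr` (rates, quartile incidence table, multivariate logistic
#' model), `simulate` (30- vs 60-min arms), `expose` (per-subject exposure
#' and the duration comparison), `vpc` — writing tidy CSVs into the output
#' directory. Every CSV gets a sidecar `.meta.json` recording the config
#' hash and seed, so reruns are auditable; outputs are deterministic given
#' `(config, seed)`. Validation happens before any stage runs.
#'
#' @param config Path to a YAML run config, or an equivalent list. Blocks:
#'   `stages` (character vector), `seed`, `model` (see
#'   [read_poppk_config()]), `scenario` (`dose_per_kg`, `schedule`,
#'   `n_cycles`, `n_subjects`, `durations_min`), `cohort` (arguments of
#'   [cohort_spec()]), `analysis` (`rate_mode`: `"observed"` or
#'   `"sensitivity60"`; `exclude_outliers`; optional `cohort_csv`).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.list(config)) config else yaml::read_yaml(config)
  validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg)
  seed <- as.integer(cfg$seed)
  paths <- list()
  cohort <- NULL

  if ("generate" %in% cfg$stages) {
    spec <- do.call(cohort_spec, c(cfg$cohort %||% list(), list(seed = seed)))
    cohort <- generate_irr_cohort(spec)
    paths$cohort <- write_with_sidecar(
      cohort, file.path(out_dir, "cohort.csv"), cfg_hash, seed)
  }
  if ("irr" %in% cfg$stages) {
    if (is.null(cohort)) {
      cohort <- readr::read_csv(cfg$analysis$cohort_csv,
                                show_col_types = FALSE)
    }
    mode <- cfg$analysis$rate_mode %||% "observed"
    rated <- if (identical(mode, "sensitivity60")) {
      sensitivity_rate(cohort)
    } else {
      compute_infusion_rate(cohort)
    }
    if (isTRUE(cfg$analysis$exclude_outliers) && "is_outlier" %in% names(rated)) {
      rated <- rated[!rated$is_outlier, ]
    }
    grouped <- quartile_groups(rated)
    tab <- incidence_table(grouped)
    fit <- logistic_model(grouped)
    paths$incidence <- write_with_sidecar(
      tab, file.path(out_dir, "incidence_by_quartile.csv"), cfg_hash, seed)
    paths$logistic <- write_with_sidecar(
      tidy.irr_fit(fit), file.path(out_dir, "logistic_model.csv"),
      cfg_hash, seed)
  }
  if ("simulate" %in% cfg$stages) {
    pop <- read_poppk_config(cfg$model)
    sc <- cfg$scenario
    pool <- withr::with_seed(seed + 7L, {
      stats::rlnorm(max(2 * sc$n_subjects, 100), log(sc$weight_median %||% 65),
                    sqrt(log(1 + (sc$weight_cv %||% 0.2)^2)))
    })
    arms <- lapply(sc$durations_min %||% c(30, 60), function(dur) {
      simulate_arm(pop, scenario_regimen(sc, dur), n = sc$n_subjects,
                   weight_pool = pool, seed = seed)
    })
    names(arms) <- paste0("dur", sc$durations_min %||% c(30, 60))
    prof <- dplyr::bind_rows(lapply(names(arms), function(nm) {
      dplyr::mutate(arms[[nm]]$profiles, arm = nm, .before = 1)
    }))
    paths$profiles <- write_with_sidecar(
      prof, file.path(out_dir, "profiles.csv"), cfg_hash, seed)
    if ("expose" %in% cfg$stages) {
      expo <- dplyr::bind_rows(lapply(names(arms), function(nm) {
        dplyr::mutate(arm_exposure(arms[[nm]], interval = "first_dose"),
                      arm = nm, .before = 1)
      }))
      paths$exposure <- write_with_sidecar(
        expo, file.path(out_dir, "exposure.csv"), cfg_hash, seed)
      if (length(arms) == 2) {
        cmpr <- exposure_comparison(expo[expo$arm == names(arms)[1], ],
                                    expo[expo$arm == names(arms)[2], ])
        paths$exposure_ratios <- write_with_sidecar(
          cmpr$ratios, file.path(out_dir, "exposure_ratios.csv"),
          cfg_hash, seed)
      }
    }
  }
  if ("vpc" %in% cfg$stages) {
    pop <- read_poppk_config(cfg$model)
    sc <- cfg$scenario
    reg <- scenario_regimen(sc, (sc$durations_min %||% 60)[1])
    horizon <- reg$n_cycles * regimen_tau(reg)
    des <- pk_design_spec(
      n_subjects = sc$n_subjects, reg = reg,
      sampling_times_h = sc$vpc_sampling_times_h %||%
        seq(1, horizon, length.out = 12),
      seed = seed + 11L)
    ds <- generate_pk_dataset(des, pop)
    summ <- vpc(attr(ds, "observations"), pop, reg,
                n_sim = sc$vpc_n_sim %||% 100, seed = seed + 12L)
    paths$vpc <- write_with_sidecar(
      tibble::as_tibble(summ), file.path(out_dir, "vpc_summary.csv"),
      cfg_hash, seed)
  }
  invisible(paths)
}

#' Plot simulated concentration profiles of one or two arms
#'
#' Median and 5th--95th percentile band over subjects, per arm.
#'
#' @param ... Named `arm_simulation` objects (names label the arms).
#' @param window Optional time window `c(from_h, to_h)`.
#' @return A ggplot object.
#' @export
plot_profile_bands <- function(..., window = NULL) {
  arms <- list(...)
  stopifnot(length(arms) >= 1, !is.null(names(arms)))
  d <- dplyr::bind_rows(lapply(names(arms), function(nm) {
    dplyr::mutate(arms[[nm]]$profiles, arm = nm)
  }))
  if (!is.null(window)) {
    d <- d[d$time_h >= window[1] & d$time_h <= window[2], ]
  }
  d <- d |>
    dplyr::group_by(.data$arm, .data$time_h) |>
    dplyr::summarise(
      p5 = stats::quantile(.data$conc_ug_ml, 0.05),
      p50 = stats::median(.data$conc_ug_ml),
      p95 = stats::quantile(.data$conc_ug_ml, 0.95),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, colour = .data$arm,
                                  fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50)) +
    ggplot2::labs(x = "Time since first dose (h)",
                  y = expression(paste("Concentration (", mu, "g/mL)")),
                  title = "Simulated concentration-time profiles")
}
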