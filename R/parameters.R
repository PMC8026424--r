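#' Construct a population-PK parameter set
#'
#' Container for the fixed effects, body-weight covariate exponents,
#' between-subject variance--covariance matrix and residual-error terms of a
#' two-compartment infusion model with sigmoidal time-varying clearance,
#'
#' \deqn{CL(t) = CL_0 \exp\!\left(\frac{E_{max}\, t^{\gamma}}{T_{50}^{\gamma} + t^{\gamma}}\right),}
#'
#' where \eqn{t} is continuous time since the first dose (never reset by later
#' doses). \eqn{T_{50}} is supplied in days and stored internally in hours.
#'
#' @param cl0_pop Typical clearance at first dose (L/h).
#' @param v1_pop Typical central volume (L).
#' @param q Inter-compartmental clearance (L/h).
#' @param v2_pop Typical peripheral volume (L).
#' @param emax Maximal fractional change in log-clearance (dimensionless;
#'   negative values describe clearance that falls over time, as is typical
#'   for monoclonal antibodies).
#' @param t50_days Time at half-maximal clearance change, in days.
#' @param gamma Sigmoidicity exponent (>= 0).
#' @param theta_wt_cl,theta_wt_v1 Allometric body-weight exponents on
#'   clearance and central volume.
#' @param wt_ref Reference body weight (kg).
#' @param omega 4x4 symmetric positive-semidefinite variance--covariance
#'   matrix of the random effects (eta_cl, eta_v1, eta_v2, eta_emax); build
#'   one with [omega_matrix()].
#' @param sigma_add Additive residual SD (ug/mL).
#' @param sigma_prop Proportional residual SD (dimensionless).
#'
#' @return An object of class `poppk_parameters` (a named list; `t50` is in
#'   hours).
#' @seealso [default_poppk_parameters()], [clearance_at_time()],
#'   [apply_weight_covariates()]
#' @export
poppk_parameters <- function(cl0_pop, v1_pop, q, v2_pop,
                             emax = 0, t50_days = 27, gamma = 2,
                             theta_wt_cl = 0.75, theta_wt_v1 = 1,
                             wt_ref = 70,
                             omega = omega_matrix(),
                             sigma_add = 0, sigma_prop = 0) {
  for (nm in c("cl0_pop", "v1_pop", "q", "v2_pop", "t50_days", "gamma",
               "theta_wt_cl", "theta_wt_v1", "wt_ref",
               "sigma_add", "sigma_prop", "emax")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (cl0_pop <= 0 || v1_pop <= 0 || v2_pop <= 0 || wt_ref <= 0) {
    stop("clearances, volumes and the reference weight must be positive",
         call. = FALSE)
  }
  if (q < 0) stop("`q` must be non-negative", call. = FALSE)
  if (t50_days <= 0) stop("`t50_days` must be positive", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  if (sigma_add < 0 || sigma_prop < 0) {
    stop("residual SDs must be non-negative", call. = FALSE)
  }
  omega <- validate_omega(omega)

  structure(
    list(
      cl0_pop = cl0_pop, v1_pop = v1_pop, q = q, v2_pop = v2_pop,
      emax = emax, t50 = t50_days * 24, gamma = gamma,
      theta_wt_cl = theta_wt_cl, theta_wt_v1 = theta_wt_v1,
      wt_ref = wt_ref, omega = omega,
      sigma_add = sigma_add, sigma_prop = sigma_prop
    ),
    class = "poppk_parameters"
  )
}

eta_names <- c("eta_cl", "eta_v1", "eta_v2", "eta_emax")

#' Build a random-effects variance--covariance matrix
#'
#' Convenience constructor for the 4x4 omega matrix from its lower-triangular
#' entries: variances for clearance, central volume, peripheral volume and
#' Emax, plus the two covariances the model carries (CL--V1 and CL--Emax).
#'
#' @param var_cl,var_v1,var_v2,var_emax Variances of the eta terms. The first
#'   three act on the log scale (exponential between-subject variability);
#'   `var_emax` is additive on Emax.
#' @param cov_cl_v1,cov_cl_emax Covariances.
#' @return A named, symmetric 4x4 matrix.
#' @export
omega_matrix <- function(var_cl = 0, var_v1 = 0, var_v2 = 0, var_emax = 0,
                         cov_cl_v1 = 0, cov_cl_emax = 0) {
  om <- diag(c(var_cl, var_v1, var_v2, var_emax))
  om[1, 2] <- om[2, 1] <- cov_cl_v1
  om[1, 4] <- om[4, 1] <- cov_cl_emax
  dimnames(om) <- list(eta_names, eta_names)
  om
}

validate_omega <- function(omega) {
  if (!is.matrix(omega) || !identical(dim(omega), c(4L, 4L))) {
    stop("`omega` must be a 4x4 matrix (eta_cl, eta_v1, eta_v2, eta_emax)",
         call. = FALSE)
  }
  if (max(abs(omega - t(omega))) > 1e-10) {
    stop("`omega` must be symmetric", call. = FALSE)
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("`omega` must be positive semi-definite", call. = FALSE)
  }
  dimnames(omega) <- list(eta_names, eta_names)
  omega
}

#' Illustrative default parameter set
#'
#' A documented, illustrative ramucirumab-like parameter set on the scale of
#' published monoclonal-antibody population-PK models: clearance ~0.015 L/h,
#' central volume ~5.4 L, modest peripheral distribution, clearance declining
#' ~18% over treatment with half-maximal change at 27 days. These defaults
#' exist so that examples and simulations run out of the box; any real
#' analysis supplies its own estimates via [poppk_parameters()] or a YAML
#' config ([read_poppk_config()]).
#'
#' @return A `poppk_parameters` object.
#' @export
default_poppk_parameters <- function() {
  poppk_parameters(
    cl0_pop = 0.015, v1_pop = 5.4, q = 0.016, v2_pop = 2.9,
    emax = -0.2, t50_days = 27, gamma = 2,
    theta_wt_cl = 0.75, theta_wt_v1 = 1, wt_ref = 70,
    omega = omega_matrix(var_cl = 0.09, var_v1 = 0.04, var_v2 = 0.25,
                         var_emax = 0.01, cov_cl_v1 = 0.03,
                         cov_cl_emax = 0.005),
    sigma_add = 1, sigma_prop = 0.2
  )
}

#' @export
print.poppk_parameters <- function(x, ...) {
  cat("<poppk_parameters>\n")
  cat(sprintf("  CL0 %.4g L/h  V1 %.4g L  Q %.4g L/h  V2 %.4g L\n",
              x$cl0_pop, x$v1_pop, x$q, x$v2_pop))
  cat(sprintf("  Emax %.4g  T50 %.4g days  gamma %.4g\n",
              x$emax, x$t50 / 24, x$gamma))
  cat(sprintf("  weight exponents: CL %.3g, V1 %.3g (ref %.4g kg)\n",
              x$theta_wt_cl, x$theta_wt_v1, x$wt_ref))
  cat(sprintf("  residual: additive %.3g ug/mL, proportional %.3g\n",
              x$sigma_add, x$sigma_prop))
  cat("  omega diagonal:",
      paste(sprintf("%.3g", diag(x$omega)), collapse = ", "), "\n")
  invisible(x)
}

.cl_sigmoid <- function(t, cl0, emax, t50, gamma) {
  # t^gamma/(t50^gamma + t^gamma) in log space to dodge overflow at large t
  frac <- ifelse(t == 0 & gamma > 0, 0,
                 1 / (1 + exp(gamma * (log(t50) - log(pmax(t, .Machine$double.xmin))))))
  if (gamma == 0) frac <- rep(0.5, length(t))
  cl0 * exp(emax * frac)
}

#' Clearance as a function of time since first dose
#'
#' Evaluates the sigmoidal time-varying clearance
#' \eqn{CL(t) = CL_0 \exp(E_{max} t^\gamma / (T_{50}^\gamma + t^\gamma))}.
#' Time is continuous time since the first dose and is never reset by
#' subsequent doses. With `gamma = 0` the sigmoid term is the constant 1/2.
#'
#' @param p A `poppk_parameters` object (typical values are used), or a
#'   one-row data frame of individual parameters as produced by
#'   [sample_population()] (columns `cl0_i`, `emax_i`), in which case `p`
#'   must carry `t50`/`gamma` columns or they are taken from `model`.
#' @param t Time(s) since first dose, hours. Must be non-negative.
#' @param model Optional `poppk_parameters` supplying `t50` and `gamma` when
#'   `p` is an individual-parameter row.
#' @return Numeric vector of clearances (L/h), same length as `t`.
#' @export
clearance_at_time <- function(p, t, model = NULL) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative (hours since first dose)",
         call. = FALSE)
  }
  if (inherits(p, "poppk_parameters")) {
    return(.cl_sigmoid(t, p$cl0_pop, p$emax, p$t50, p$gamma))
  }
  if (is.data.frame(p) && nrow(p) == 1L && all(c("cl0_i", "emax_i") %in% names(p))) {
    if (is.null(model)) stop("supply `model` for t50/gamma with individual parameters",
                             call. = FALSE)
    return(.cl_sigmoid(t, p$cl0_i, p$emax_i, model$t50, model$gamma))
  }
  stop("`p` must be poppk_parameters or a one-row individual-parameter frame",
       call. = FALSE)
}

#' Apply allometric body-weight covariates to the typical values
#'
#' Scales typical clearance and central volume by the allometric power model
#' \eqn{\theta (W/W_{ref})^{\theta_{wt}}}; inter-compartmental clearance and
#' peripheral volume carry no covariate.
#'
#' @param pop A `poppk_parameters` object.
#' @param weight Body weight(s) in kg, positive.
#' @return A tibble with one row per weight: `weight`, `cl0`, `v1`, `q`, `v2`.
#' @export
apply_weight_covariates <- function(pop, weight) {
  stopifnot(inherits(pop, "poppk_parameters"))
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be positive and finite", call. = FALSE)
  }
  ratio <- weight / pop$wt_ref
  tibble::tibble(
    weight = weight,
    cl0 = pop$cl0_pop * ratio^pop$theta_wt_cl,
    v1 = pop$v1_pop * ratio^pop$theta_wt_v1,
    q = pop$q,
    v2 = pop$v2_pop
  )
}
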