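# Shared fixture builders; everything is generated in code at test time.

test_params <- function(emax = -0.2, sigma_add = 1, sigma_prop = 0.2,
                        omega = omega_matrix(var_cl = 0.09, var_v1 = 0.04,
                                             var_v2 = 0.25, var_emax = 0.01,
                                             cov_cl_v1 = 0.03,
                                             cov_cl_emax = 0.005)) {
  poppk_parameters(cl0_pop = 0.015, v1_pop = 5.4, q = 0.016, v2_pop = 2.9,
                   emax = emax, t50_days = 27, gamma = 2,
                   theta_wt_cl = 0.75, theta_wt_v1 = 1, wt_ref = 70,
                   omega = omega, sigma_add = sigma_add,
                   sigma_prop = sigma_prop)
}

# random constant-clearance parameter set on a plausible mAb-to-small-protein
# scale, for oracle comparisons
random_const_cl_individual <- function() {
  list(cl0_i = stats::runif(1, 0.005, 0.08),
       v1_i = stats::runif(1, 2, 10),
       v2_i = stats::runif(1, 1, 10),
       q_i = stats::runif(1, 0.005, 0.08),
       emax_i = 0)
}

const_cl_model <- function() {
  poppk_parameters(cl0_pop = 0.015, v1_pop = 5.4, q = 0.016, v2_pop = 2.9,
                   emax = 0, t50_days = 27, gamma = 2)
}

# cohort of bare counts: n_events of n_total records carry the event flag,
# all in a single group; used to reproduce printed incidence cells
count_records <- function(n_events, n_total, grade3_events = 0) {
  tibble::tibble(
    irr_flag = seq_len(n_total) <= n_events,
    irr_grade_ge3 = seq_len(n_total) <= grade3_events,
    grp = "all"
  )
}
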