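# Illustrative population-PK parameter set (ramucirumab-like scale).
# Supply estimates from your own analysis for real work.
cl0_pop: 0.015      # L/h, clearance at first dose
v1_pop: 5.4         # L, central volume
q: 0.016            # L/h, inter-compartmental clearance
v2_pop: 2.9         # L, peripheral volume
emax: -0.2          # maximal fractional change in log-clearance
t50_days: 27        # days to half-maximal clearance change
gamma: 2            # sigmoidicity
theta_wt_cl: 0.75   # allometric exponent on CL
theta_wt_v1: 1.0    # allometric exponent on V1
wt_ref: 70          # kg
omega_var_cl: 0.09
omega_var_v1: 0.04
omega_var_v2: 0.25
omega_var_emax: 0.01
omega_cov_cl_v1: 0.03
omega_cov_cl_emax: 0.005
sigma_add: 1        # ug/mL
sigma_prop: 0.2
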