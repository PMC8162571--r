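# Shared fixture builders: small phantoms and simulated exams built in
# code at test time.

std_protocols <- default_protocols()

# One muscle (whole disc) plus background: large connected ROI, handy
# for curve-level checks.
single_tissue <- function(trate = 71.09, T1 = 1400, T2 = 33, T2star = 27,
                          ff = 0.05, M0 = 1000) {
  list(tissue_spec("TA", 1L, T1 = T1, T2 = T2, T2star = T2star,
                   fat_fraction = ff, trate = trate, M0 = M0),
       tissue_spec("background", 0L, T1 = 500, T2 = 50, T2star = 20,
                   M0 = 1e-3))
}

# Simulated dynamic series + fitted baseline T1 for one uniform tissue.
make_scene <- function(trate = 71.09, C_eq = 0.08, grid = c(16, 16, 2),
                       noise_sd = 0, seed = 1, r1 = 4.5, T1 = 1400,
                       T2star = 27, M0 = 1000, k_washin = 0.02) {
  tiss <- single_tissue(trate = trate, T1 = T1, T2star = T2star, M0 = M0)
  ph <- build_phantom(tiss, grid, geometry_seed = seed)
  km <- kinetic_model(t_arrival = 90, C_eq = C_eq, k_washin = k_washin)
  dyn <- simulate_acquisition(ph, std_protocols$dynamic, kinetics = km,
                              agent = contrast_agent(r1),
                              noise_sd = noise_sd, seed = seed)
  vfa <- simulate_acquisition(ph, std_protocols$vfa, noise_sd = noise_sd,
                              seed = seed + 1)
  t1fit <- fit_vfa_t1(vfa$data, std_protocols$vfa$flip_angles,
                      std_protocols$vfa$TR)
  list(phantom = ph, dynamic = dyn, t1 = t1fit, kinetics = km,
       tissues = tiss)
}

# Cohort means/SDs used as simulator operating points (healthy control
# and disease-affected TRATE per muscle).
trate_cohort_params <- function() {
  data.frame(
    muscle = c("TA", "PL", "TP", "MG", "LG"),
    mean_case = c(27.67, 52.75, 43.94, 58.72, 50.39),
    sd_case = c(5.54, 8.76, 10.02, 10.49, 12.67),
    mean_ref = c(71.09, 80.50, 83.80, 89.56, 85.81),
    sd_ref = c(13.52, 15.52, 15.14, 15.35, 13.71))
}
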