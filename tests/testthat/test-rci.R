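te_dyn <- std_protocols$dynamic$TE_list

test_that("two-echo R2* and TE-zero extrapolation follow closed forms", {
  expect_equal(r2star_from_dual_echo(100, 100, te_dyn[1], te_dyn[2]), 0)
  # S1/S2 = e over the 18.94 ms echo spacing
  expect_equal(r2star_from_dual_echo(exp(1), 1, te_dyn[1], te_dyn[2]),
               52.7983104540655, tolerance = 1e-12)
  expect_true(is.na(r2star_from_dual_echo(-1, 2, te_dyn[1], te_dyn[2])))
  expect_error(r2star_from_dual_echo(1, 1, 20, 1.06), "TE2")

  # S0 = S1 exp(TE1 R2*), frozen closed-form value
  r2s <- 52.7983104540655
  S2 <- 100 * exp(-(te_dyn[2] - te_dyn[1]) / 1000 * r2s)
  expect_equal(extrapolate_te_zero(100, S2, te_dyn[1], te_dyn[2]),
               105.756194714306, tolerance = 1e-9)
  # TE1 -> 0 limit: S0 -> S1
  expect_equal(extrapolate_te_zero(100, 90, 1e-9, 20), 100,
               tolerance = 1e-6)

  # forward-model voxel: S0 equals the TE = 0 SPGR signal
  s1 <- spgr_signal(1400, 27, 1000, 21, te_dyn[1], 25)
  s2 <- spgr_signal(1400, 27, 1000, 21, te_dyn[2], 25)
  expect_equal(extrapolate_te_zero(s1, s2, te_dyn[1], te_dyn[2]),
               spgr_signal(1400, 27, 1000, 21, 0, 25), tolerance = 1e-9)
  expect_equal(r2star_from_dual_echo(s1, s2, te_dyn[1], te_dyn[2]),
               1000 / 27, tolerance = 1e-9)
})

test_that("delta-R1 inversion is self-calibrating and exact on the
           forward model", {
  T1b <- 1400; TR <- 21; fa <- 25
  tax <- (0:149) * 5.2
  ct <- concentration_truth(kinetic_model(C_eq = 0.08), tax)
  R1t <- 1000 / T1b + 4.5 * ct
  E1 <- exp(-TR / 1000 * R1t)
  a <- fa * pi / 180
  S0 <- 1000 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
  dr1 <- delta_r1_curve(S0, baseline_idx = 1:17, baseline_T1 = T1b,
                        TR = TR, flip_angle = fa)
  expect_lt(max(abs(dr1$delta_r1[1:17])), 1e-9)
  expect_equal(max(dr1$delta_r1), 4.5 * max(ct), tolerance = 1e-6)
  # r1 Ct = 0.36 1/s at the plateau recovers exactly
  expect_equal(dr1$delta_r1[150], 4.5 * ct[150], tolerance = 1e-6)

  # gain invariance: doubling the scene M0 leaves delta-R1 unchanged
  dr1b <- delta_r1_curve(2 * S0, 1:17, T1b, TR, fa)
  expect_equal(dr1b$delta_r1, dr1$delta_r1, tolerance = 1e-9)
  expect_equal(dr1b$M0, 2 * dr1$M0, tolerance = 1e-9)
})

test_that("concentration is delta-R1 over r1", {
  expect_equal(concentration(0.36, contrast_agent(r1 = 4.5)), 0.08)
  expect_equal(concentration(0, contrast_agent()), 0)
  expect_error(contrast_agent(r1 = 0), "r1")
})

test_that("TRATE is the equilibrium quotient with a concentration floor", {
  cfg <- rci_config()
  dr2 <- rep(3.8, 20); ct <- rep(0.11, 20)
  est <- trate_estimate(dr2, ct, 11:20, cfg)
  expect_equal(est$trate, 34.5454545454545, tolerance = 1e-12)
  expect_true(est$qc_pass)
  # both modes coincide on constant curves
  cfg2 <- rci_config(trate_mode = "mean_of_ratios")
  expect_equal(trate_estimate(dr2, ct, 11:20, cfg2)$trate, est$trate)
  # concentration floor: no arrival -> undefined TRATE
  expect_error(trate_estimate(dr2, rep(0.001, 20), 11:20, cfg),
               "floor")
  # negative estimate flags QC
  est_neg <- trate_estimate(-dr2, ct, 11:20, cfg)
  expect_false(est_neg$qc_pass)
})

test_that("noise-free pipeline recovers TRATE to 1e-6 over the operating
           range, monotonically and dose-invariantly", {
  set.seed(5)
  for (i in 1:4) {
    tr <- runif(1, 10, 120); ceq <- runif(1, 0.05, 0.2)
    sc <- make_scene(trate = tr, C_eq = ceq, grid = c(12, 12, 2))
    fit <- rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels)
    expect_lt(abs(coef(fit)[["1"]] / tr - 1), 1e-6)
    expect_true(all(fit$table$qc_pass))
  }

  est <- vapply(c(20, 50, 90), function(tr) {
    sc <- make_scene(trate = tr, C_eq = 0.1, grid = c(12, 12, 2))
    coef(rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels))[["1"]]
  }, numeric(1))
  expect_true(all(diff(est) > 0))

  # doubling the dose leaves TRATE unchanged (linear regime)
  a <- make_scene(trate = 46.7, C_eq = 0.08, grid = c(12, 12, 2))
  b <- make_scene(trate = 46.7, C_eq = 0.16, grid = c(12, 12, 2))
  ta <- coef(rci_fit(a$dynamic, a$t1$T1, labels = a$phantom$labels))[["1"]]
  tb <- coef(rci_fit(b$dynamic, b$t1$T1, labels = b$phantom$labels))[["1"]]
  expect_lt(abs(tb / ta - 1), 1e-6)
})

test_that("all curve outputs are invariant to a global signal gain", {
  sc <- make_scene(trate = 60, C_eq = 0.1, grid = c(12, 12, 2),
                   noise_sd = 0)
  fit1 <- rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels)
  dyn2 <- sc$dynamic
  dyn2$data <- 3.14 * dyn2$data
  fit2 <- rci_fit(dyn2, sc$t1$T1, labels = sc$phantom$labels)
  r1 <- fit1$rois[["1"]]; r2 <- fit2$rois[["1"]]
  expect_equal(r2$delta_r2star_t, r1$delta_r2star_t, tolerance = 1e-9)
  expect_equal(r2$delta_r1_t, r1$delta_r1_t, tolerance = 1e-9)
  expect_equal(r2$Ct_t, r1$Ct_t, tolerance = 1e-9)
  expect_equal(r2$trate, r1$trate, tolerance = 1e-9)
})

test_that("ROI-curve TRATE stays within 3% of truth at SNR 50 across
           seeded noise realizations", {
  # >= 200-voxel ROI; baseline SNR defined on the first-echo signal
  tiss <- single_tissue(trate = 46.7)
  ph <- build_phantom(tiss, c(16, 16, 2), geometry_seed = 1)
  expect_gt(sum(ph$labels == 1), 200)
  km <- kinetic_model(C_eq = 0.11)
  s1 <- spgr_signal(1400, 27, 1000, 21, te_dyn[1], 25)
  t1map <- ifelse(ph$labels == 1, 1400, NA_real_)
  errs <- vapply(1:100, function(s) {
    dyn <- simulate_acquisition(ph, std_protocols$dynamic, km,
                                noise_sd = s1 / 50, seed = s)
    fit <- rci_fit(dyn, t1map, labels = ph$labels)
    abs(coef(fit)[["1"]] / 46.7 - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.03)

  # ratio-of-means and mean-of-ratios agree closely on a true plateau
  dyn <- simulate_acquisition(ph, std_protocols$dynamic, km,
                              noise_sd = s1 / 50, seed = 7)
  t_rom <- coef(rci_fit(dyn, t1map, labels = ph$labels))[["1"]]
  t_mor <- coef(rci_fit(dyn, t1map, labels = ph$labels,
                        config = rci_config(trate_mode =
                                              "mean_of_ratios")))[["1"]]
  expect_lt(abs(t_rom / t_mor - 1), 0.005)
})

test_that("voxelwise-then-aggregate mode matches ROI-curve mode on a
           noise-free uniform tissue", {
  sc <- make_scene(trate = 71.09, C_eq = 0.08, grid = c(12, 12, 2))
  f1 <- rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels)
  f2 <- rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels,
                config = rci_config(roi_mode = "voxelwise_then_aggregate"))
  expect_equal(coef(f2)[["1"]], coef(f1)[["1"]], tolerance = 1e-6)
  expect_false(is.null(f2$trate_map))
  expect_true(all(is.na(f2$trate_map[sc$phantom$labels == 0])))
})

test_that("analysis windows are validated and flagged points counted", {
  sc <- make_scene(grid = c(12, 12, 2))
  bad <- rci_config(baseline_window = 135:150)
  expect_error(rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels,
                       config = bad), "overlap")
  # baseline curves hover around zero concentration
  fit <- rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels)
  expect_true(all(vapply(fit$rois, function(r) isTRUE(r$baseline_ct_zero),
                         logical(1))))
  expect_lt(max(abs(fit$rois[["1"]]$Ct_t[fit$windows$baseline])), 1e-9)
})

test_that("rci_fit S3 surface: print, summary, coef, plot", {
  sc <- make_scene(grid = c(12, 12, 2))
  fit <- rci_fit(sc$dynamic, sc$t1$T1, labels = sc$phantom$labels)
  expect_named(coef(fit), "1")
  s <- summary(fit)
  expect_s3_class(s, "summary.rci_fit")
  expect_true(all(c("trate", "ct_eq_mean", "qc_pass") %in% names(s)))
  expect_output(print(fit), "Relaxivity contrast fit")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})
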