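# Relaxivity contrast imaging core: converts the dual-echo dynamic
# series into delta-R2*(t), delta-R1(t), the tissue contrast-agent
# concentration Ct(t) = delta-R1/r1, and the transverse relaxivity at
# tracer equilibrium TRATE = delta-R2*/Ct over the equilibrium window.

#' Two-echo R2* estimate
#'
#' `R2* = log(S1/S2) / (TE2 - TE1)` with echo times converted to
#' seconds. Non-positive signals yield NA (the caller flags and excludes
#' those points from analysis windows).
#'
#' @param S1,S2 Magnitudes at the first/second echo (vectorized).
#' @param TE1,TE2 Echo times in ms, `TE2 > TE1`.
#' @return R2* in s^-1.
#' @examples
#' r2star_from_dual_echo(exp(1), 1, 1.06, 20.0)  # 1/0.01894 s^-1
#' @export
r2star_from_dual_echo <- function(S1, S2, TE1, TE2) {
  if (TE2 <= TE1) stop("TE2 must exceed TE1")
  r <- S1 / S2
  ok <- (S1 > 0) & (S2 > 0) & is.finite(r)
  out <- rep(NA_real_, length(r))
  dim(out) <- dim(r)
  out[ok] <- log(r[ok]) / ((TE2 - TE1) / 1000)
  out
}

#' Extrapolate the dual-echo signal to TE = 0
#'
#' Log-linear extrapolation of the two echoes to zero echo time,
#' `S0 = S1 * exp(TE1 * R2*)`, removing the T2* decay so that the
#' remaining signal depends on T1 (and M0) only. This is the signal the
#' longitudinal-rate inversion ([delta_r1_curve()]) operates on.
#'
#' @inheritParams r2star_from_dual_echo
#' @return S0 in the same units as S1; NA where either echo is
#'   non-positive.
#' @export
extrapolate_te_zero <- function(S1, S2, TE1, TE2) {
  r2s <- r2star_from_dual_echo(S1, S2, TE1, TE2)
  S1 * exp((TE1 / 1000) * r2s)
}

#' Analysis configuration for the dynamic series
#'
#' @param baseline_window Integer frame indices of the pre-contrast
#'   baseline, or `NULL` (default) to use all frames acquired strictly
#'   before the injection time minus `baseline_guard` frames.
#' @param equilibrium_frames Number of frames at the end of the series
#'   forming the tracer-equilibrium window (default 10).
#' @param r1 Contrast-agent longitudinal relaxivity, L mmol^-1 s^-1.
#' @param trate_mode `"ratio_of_means"` (default; TRATE = mean dR2* over
#'   the window divided by mean Ct, less noise-biased) or
#'   `"mean_of_ratios"` (mean of pointwise quotients).
#' @param roi_mode `"roi_curve_first"` (default; average signals over
#'   the ROI, then compute curves and TRATE — better SNR) or
#'   `"voxelwise_then_aggregate"` (voxelwise TRATE map, then ROI mean).
#' @param ct_floor Minimum admissible equilibrium-mean concentration in
#'   mM (default 0.01); below it TRATE is undefined (no contrast
#'   arrival) and an error is raised.
#' @param baseline_guard Frames dropped from the end of the baseline
#'   window as a guard against partial-arrival contamination (default 1).
#' @param qc_max_flagged Maximal tolerated fraction of flagged points
#'   inside a window before the fit's QC fails (default 0.2).
#' @return Object of class `rci_config`.
#' @export
rci_config <- function(baseline_window = NULL, equilibrium_frames = 10,
                       r1 = 4.5, trate_mode = c("ratio_of_means",
                                                "mean_of_ratios"),
                       roi_mode = c("roi_curve_first",
                                    "voxelwise_then_aggregate"),
                       ct_floor = 0.01, baseline_guard = 1,
                       qc_max_flagged = 0.2) {
  if (r1 <= 0) stop("r1 must be > 0")
  if (equilibrium_frames < 1) stop("equilibrium_frames must be >= 1")
  structure(list(baseline_window = baseline_window,
                 equilibrium_frames = as.integer(equilibrium_frames),
                 r1 = r1, trate_mode = match.arg(trate_mode),
                 roi_mode = match.arg(roi_mode), ct_floor = ct_floor,
                 baseline_guard = as.integer(baseline_guard),
                 qc_max_flagged = qc_max_flagged),
            class = "rci_config")
}

.resolve_windows <- function(time_axis, injection_time, config) {
  nt <- length(time_axis)
  bw <- config$baseline_window
  if (is.null(bw)) {
    bw <- which(time_axis < injection_time)
    if (config$baseline_guard > 0 && length(bw) > config$baseline_guard)
      bw <- bw[seq_len(length(bw) - config$baseline_guard)]
  }
  ew <- seq.int(nt - config$equilibrium_frames + 1L, nt)
  if (length(bw) == 0) stop("baseline window is empty")
  if (any(ew < 1)) stop("equilibrium window exceeds the series length")
  if (length(intersect(bw, ew)) > 0)
    stop("baseline and equilibrium windows overlap")
  list(baseline = bw, equilibrium = ew)
}

#' Longitudinal relaxation-rate change from the TE-zero dynamic signal
#'
#' Self-calibrating inversion of the SPGR signal equation. The
#' equilibrium magnetization M0 is calibrated from the baseline-window
#' mean of `S0(t)` together with the pre-contrast T1; each frame is then
#' inverted for `E1 = exp(-TR * R1)` via
#' `E1 = (M0 sin a - S0) / (M0 sin a - S0 cos a)`, giving
#' `R1(t) = -log(E1)/TR` and `dR1(t) = R1(t) - 1/T1_baseline` (s^-1).
#' Frames where the inversion leaves (0, 1) are flagged as NA.
#'
#' Because of the self-calibration, dR1 is invariant to a global signal
#' gain.
#'
#' @param S0_t TE-extrapolated signal per time point.
#' @param baseline_idx Frame indices of the pre-contrast baseline.
#' @param baseline_T1 Pre-contrast T1 in ms (from the VFA fit).
#' @param TR Repetition time of the dynamic sequence, ms.
#' @param flip_angle Flip angle of the dynamic sequence, degrees.
#' @return List with `delta_r1` (s^-1 per frame, NA where flagged),
#'   `M0` (calibrated), `n_flagged`.
#' @export
delta_r1_curve <- function(S0_t, baseline_idx, baseline_T1, TR, flip_angle) {
  if (!is.finite(baseline_T1) || baseline_T1 <= 0)
    stop("baseline_T1 must be positive")
  base <- S0_t[baseline_idx]
  base <- base[is.finite(base) & base > 0]
  if (length(base) == 0) stop("baseline window empty after QC exclusions")
  a <- flip_angle * pi / 180
  E1b <- exp(-TR / baseline_T1)
  S0b <- mean(base)
  M0 <- S0b * (1 - E1b * cos(a)) / (sin(a) * (1 - E1b))
  E1 <- (M0 * sin(a) - S0_t) / (M0 * sin(a) - S0_t * cos(a))
  bad <- !is.finite(E1) | E1 <= 0 | E1 >= 1
  E1[bad] <- NA_real_
  R1 <- -log(E1) / (TR / 1000)                # s^-1
  dr1 <- R1 - 1000 / baseline_T1
  list(delta_r1 = dr1, M0 = M0, n_flagged = sum(bad))
}

#' Contrast-agent concentration from delta-R1
#'
#' `Ct(t) = dR1(t) / r1`, in mM.
#'
#' @param delta_r1_t Longitudinal rate change per time point, s^-1.
#' @param agent A [contrast_agent()] (or anything with an `r1` field).
#' @return Concentration per time point, mM.
#' @examples
#' concentration(0.36, contrast_agent(r1 = 4.5))  # 0.08 mM
#' @export
concentration <- function(delta_r1_t, agent = contrast_agent()) {
  if (agent$r1 <= 0) stop("r1 must be > 0")
  delta_r1_t / agent$r1
}

#' TRATE from equilibrium-window curves
#'
#' The transverse relaxivity at tracer equilibrium is the quotient of
#' the contrast-induced R2* change and the contrast concentration over
#' the equilibrium window: by default the ratio of window means,
#' optionally the mean of the pointwise ratios. Flagged (NA) points are
#' excluded; the fit's QC fails when more than `qc_max_flagged` of the
#' window is flagged or the estimate is negative. An equilibrium mean
#' concentration below `ct_floor` signals absent contrast arrival and is
#' an error.
#'
#' @param delta_r2star_t,Ct_t Per-frame curves (s^-1 and mM).
#' @param equilibrium_idx Frame indices of the equilibrium window.
#' @param config An [rci_config()].
#' @return List with `trate` (mM^-1 s^-1), `dr2star_eq` and `ct_eq`
#'   (window mean +/- sd as length-2 vectors `c(mean, sd)`), `qc_pass`,
#'   `qc_reason`.
#' @export
trate_estimate <- function(delta_r2star_t, Ct_t, equilibrium_idx,
                           config = rci_config()) {
  dr2 <- delta_r2star_t[equilibrium_idx]
  ct <- Ct_t[equilibrium_idx]
  ok <- is.finite(dr2) & is.finite(ct)
  frac_flagged <- mean(!ok)
  if (all(!ok)) stop("equilibrium window empty after QC exclusions")
  mct <- mean(ct[ok]); mdr2 <- mean(dr2[ok])
  if (mct < config$ct_floor)
    stop(sprintf(paste("equilibrium concentration %.4f mM is below the",
                       "floor %.3f mM: TRATE undefined (no contrast",
                       "arrival)"), mct, config$ct_floor))
  trate <- if (config$trate_mode == "ratio_of_means") mdr2 / mct
           else mean(dr2[ok] / ct[ok])
  qc_reason <- character(0)
  if (frac_flagged > config$qc_max_flagged)
    qc_reason <- c(qc_reason, sprintf("%.0f%% of equilibrium window flagged",
                                      100 * frac_flagged))
  if (trate < 0) qc_reason <- c(qc_reason, "negative TRATE")
  list(trate = trate,
       dr2star_eq = c(mean = mdr2, sd = stats::sd(dr2[ok])),
       ct_eq = c(mean = mct, sd = stats::sd(ct[ok])),
       qc_pass = length(qc_reason) == 0,
       qc_reason = qc_reason)
}

.curve_from_signals <- function(S1_t, S2_t, TE1, TE2, TR, flip_angle,
                                baseline_T1, windows, config) {
  r2s_t <- r2star_from_dual_echo(S1_t, S2_t, TE1, TE2)
  base_r2s <- r2s_t[windows$baseline]
  if (all(!is.finite(base_r2s)))
    stop("baseline window empty after QC exclusions")
  dr2s_t <- r2s_t - mean(base_r2s, na.rm = TRUE)
  S0_t <- extrapolate_te_zero(S1_t, S2_t, TE1, TE2)
  dr1 <- delta_r1_curve(S0_t, windows$baseline, baseline_T1, TR, flip_angle)
  ct_t <- concentration(dr1$delta_r1, structure(list(r1 = config$r1),
                                                class = "contrast_agent"))
  est <- trate_estimate(dr2s_t, ct_t, windows$equilibrium, config)
  bl_ct <- ct_t[windows$baseline]
  bl_sd <- stats::sd(bl_ct, na.rm = TRUE)
  baseline_ok <- !is.finite(bl_sd) || bl_sd == 0 ||
    abs(mean(bl_ct, na.rm = TRUE)) < 3 * bl_sd
  c(est,
    list(delta_r2star_t = dr2s_t, Ct_t = ct_t, delta_r1_t = dr1$delta_r1,
         n_flagged_r1 = dr1$n_flagged, baseline_ct_zero = baseline_ok))
}

#' Fit the relaxivity-contrast model to a dynamic series
#'
#' The central estimator: converts a dual-echo dynamic magnitude series
#' into per-ROI (or whole-volume) curves of delta-R2*(t), delta-R1(t)
#' and Ct(t), and the TRATE estimate over the tracer-equilibrium window.
#'
#' With `roi_mode = "roi_curve_first"` (default) the two echo signals
#' are first averaged over each ROI and one curve set per ROI is
#' analysed; with `"voxelwise_then_aggregate"` a voxelwise TRATE map is
#' computed and averaged over each ROI (the map is returned in
#' `$trate_map`).
#'
#' @param series A `dynamic_series` (from [simulate_acquisition()] or
#'   [read_volume()]): 5-D magnitude array (x, y, z, echo, time) plus
#'   echo times, time axis and injection time. A plain list with fields
#'   `data`, `protocol` (`TE_list`, `TR`, `flip_angles`), `time_axis`,
#'   `injection_time` is accepted.
#' @param baseline_t1 Pre-contrast T1: either a voxelwise map (ms, NA
#'   outside the fit mask) on the series grid, or a single value when
#'   `labels` is `NULL`.
#' @param labels Integer ROI label volume on the series grid (0 =
#'   background), or `NULL` to analyse the mean curve over all voxels
#'   with finite `baseline_t1`.
#' @param config An [rci_config()].
#' @return Object of class `rci_fit`: per-ROI results (`$rois`, a named
#'   list with curves and TRATE), `$table` (data frame: roi, trate,
#'   dr2star_eq, ct_eq, qc_pass, voxel_count), `$config`, `$windows`,
#'   `$time_axis`, and `$trate_map` in voxelwise mode.
#' @seealso [coef.rci_fit()], [summary.rci_fit()], [plot.rci_fit()]
#' @export
rci_fit <- function(series, baseline_t1, labels = NULL,
                    config = rci_config()) {
  te <- series$protocol$TE_list
  stopifnot(length(te) == 2)
  TR <- series$protocol$TR
  fa <- series$protocol$flip_angles[1]
  tax <- series$time_axis
  if (is.null(tax)) stop("dynamic series lacks a time axis")
  if (is.null(series$injection_time))
    stop("dynamic series lacks an injection time")
  windows <- .resolve_windows(tax, series$injection_time, config)
  dat <- series$data
  d <- dim(dat)
  nt <- d[length(d)]
  if (nt != length(tax)) stop("time axis does not match the series")
  spatial <- d[seq_len(length(d) - 2)]
  nvox <- prod(spatial)
  S <- array(dat, dim = c(nvox, 2, nt))

  if (is.null(labels)) {
    t1v <- if (length(baseline_t1) == 1) rep(baseline_t1, nvox)
           else as.vector(baseline_t1)
    sel <- which(is.finite(t1v))
    roi_ids <- list(whole = sel)
    t1_roi <- c(whole = mean(t1v[sel]))
  } else {
    lab <- as.vector(labels)
    if (length(lab) != nvox) stop("label volume does not match the series grid")
    t1v <- if (length(baseline_t1) == 1) rep(baseline_t1, nvox)
           else as.vector(baseline_t1)
    ids <- sort(setdiff(unique(lab), 0))
    if (length(ids) == 0) stop("label volume contains no foreground ROI")
    roi_ids <- lapply(ids, function(i) which(lab == i & is.finite(t1v)))
    names(roi_ids) <- as.character(ids)
    empty <- lengths(roi_ids) == 0
    if (any(empty)) stop("ROI(s) with no valid voxels: ",
                         paste(names(roi_ids)[empty], collapse = ", "))
    t1_roi <- vapply(roi_ids, function(ix) mean(t1v[ix]), numeric(1))
  }

  roi_mean_signal <- function(ix, e)
    colMeans(matrix(S[ix, e, , drop = FALSE], nrow = length(ix)))

  trate_map <- NULL
  rois <- list()
  if (config$roi_mode == "roi_curve_first") {
    for (nm in names(roi_ids)) {
      ix <- roi_ids[[nm]]
      rois[[nm]] <- .curve_from_signals(roi_mean_signal(ix, 1),
                                        roi_mean_signal(ix, 2),
                                        te[1], te[2], TR, fa,
                                        t1_roi[[nm]], windows, config)
      rois[[nm]]$voxel_count <- length(ix)
    }
  } else {
    trate_map <- rep(NA_real_, nvox)
    all_ix <- unique(unlist(roi_ids))
    for (v in all_ix) {
      res <- tryCatch(
        .curve_from_signals(S[v, 1, ], S[v, 2, ], te[1], te[2], TR, fa,
                            t1v[v], windows, config),
        error = function(e) NULL)
      if (!is.null(res) && res$qc_pass) trate_map[v] <- res$trate
    }
    dim(trate_map) <- spatial
    for (nm in names(roi_ids)) {
      ix <- roi_ids[[nm]]
      vals <- trate_map[ix]
      ok <- is.finite(vals)
      # representative ROI-mean curves are still reported for inspection
      cur <- .curve_from_signals(roi_mean_signal(ix, 1),
                                 roi_mean_signal(ix, 2),
                                 te[1], te[2], TR, fa,
                                 t1_roi[[nm]], windows, config)
      cur$trate <- mean(vals[ok])
      cur$voxel_count <- sum(ok)
      cur$qc_pass <- cur$qc_pass && sum(ok) > 0
      rois[[nm]] <- cur
    }
  }

  tab <- data.frame(
    roi = names(rois),
    trate = vapply(rois, function(r) r$trate, numeric(1)),
    dr2star_eq = vapply(rois, function(r) r$dr2star_eq[["mean"]], numeric(1)),
    ct_eq = vapply(rois, function(r) r$ct_eq[["mean"]], numeric(1)),
    voxel_count = vapply(rois, function(r) r$voxel_count, numeric(1)),
    qc_pass = vapply(rois, function(r) isTRUE(r$qc_pass), logical(1)),
    row.names = NULL)

  structure(list(rois = rois, table = tab, config = config,
                 windows = windows, time_axis = tax,
                 trate_map = trate_map),
            class = "rci_fit")
}

#' @export
print.rci_fit <- function(x, ...) {
  cat("Relaxivity contrast fit (", x$config$roi_mode, ", ",
      x$config$trate_mode, ")\n", sep = "")
  cat(sprintf("  baseline: %d frames; equilibrium: last %d frames\n",
              length(x$windows$baseline), length(x$windows$equilibrium)))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Extract TRATE estimates
#'
#' @param object An `rci_fit`.
#' @param ... Unused.
#' @return Named numeric vector of per-ROI TRATE values (mM^-1 s^-1).
#' @export
coef.rci_fit <- function(object, ...) {
  stats::setNames(object$table$trate, object$table$roi)
}

#' Summarize a relaxivity contrast fit
#'
#' @param object An `rci_fit`.
#' @param ... Unused.
#' @return A data frame with per-ROI TRATE, equilibrium-window mean and
#'   sd of delta-R2* and Ct, voxel counts and QC status.
#' @export
summary.rci_fit <- function(object, ...) {
  r <- object$rois
  out <- data.frame(
    roi = names(r),
    trate = vapply(r, function(z) z$trate, numeric(1)),
    dr2star_eq_mean = vapply(r, function(z) z$dr2star_eq[["mean"]], numeric(1)),
    dr2star_eq_sd = vapply(r, function(z) z$dr2star_eq[["sd"]], numeric(1)),
    ct_eq_mean = vapply(r, function(z) z$ct_eq[["mean"]], numeric(1)),
    ct_eq_sd = vapply(r, function(z) z$ct_eq[["sd"]], numeric(1)),
    voxel_count = vapply(r, function(z) z$voxel_count, numeric(1)),
    qc_pass = vapply(r, function(z) isTRUE(z$qc_pass), logical(1)),
    row.names = NULL)
  class(out) <- c("summary.rci_fit", class(out))
  out
}

#' Plot concentration and delta-R2* curves of a fit
#'
#' Two panels: Ct(t) and delta-R2*(t) for each ROI, with the baseline
#' and equilibrium windows shaded.
#'
#' @param x An `rci_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.rci_fit <- function(x, ...) {
  t <- x$time_axis
  ctm <- sapply(x$rois, function(r) r$Ct_t)
  drm <- sapply(x$rois, function(r) r$delta_r2star_t)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    for (w in x$windows) {
      rng <- range(t[w])
      graphics::rect(rng[1], graphics::par("usr")[3], rng[2],
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.3), border = NA)
    }
  }
  graphics::matplot(t, ctm, type = "l", lty = 1, xlab = "time [s]",
                    ylab = "Ct [mM]", main = "Concentration", ...)
  shade()
  graphics::matplot(t, drm, type = "l", lty = 1, xlab = "time [s]",
                    ylab = expression(Delta * R[2] * "* [1/s]"),
                    main = expression(Delta * R[2] * "*"), ...)
  shade()
  graphics::legend("bottomright", legend = names(x$rois), lty = 1,
                   col = seq_along(x$rois), bty = "n", cex = 0.8)
  invisible(x)
}
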