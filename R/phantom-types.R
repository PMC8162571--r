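#' Tissue specification for the digital calf phantom
#'
#' A `tissue_spec` holds the ground-truth MR properties of one labelled
#' tissue compartment: relaxation times, fat fraction, equilibrium
#' magnetization and the transverse relaxivity at tracer equilibrium
#' (TRATE) that the dynamic forward model uses to couple the contrast-agent
#' concentration to R2*.
#'
#' Physical ordering `T2* <= T2 <= T1` is enforced, as is
#' `fat_fraction` in \[0, 1\] and non-negative TRATE. Muscle labels must be
#' positive integers; the special tissue named `"background"` may (and by
#' default does) carry label 0, following the NIfTI segmentation
#' convention.
#'
#' @param name Tissue name. The five calf muscles use the conventional
#'   abbreviations `"TA"` (tibialis anterior), `"PL"` (peroneus longus),
#'   `"TP"` (tibialis posterior), `"MG"`/`"LG"` (medial/lateral
#'   gastrocnemius); `"background"` denotes non-tissue voxels.
#' @param label_id Integer label used in the ROI label volume.
#' @param T1,T2,T2star Relaxation times in milliseconds.
#' @param fat_fraction Proton-density fat fraction, dimensionless in \[0,1\].
#' @param trate TRATE ground truth in mM^-1 s^-1.
#' @param M0 Equilibrium magnetization, arbitrary signal units (> 0).
#' @return An object of class `tissue_spec`.
#' @examples
#' tissue_spec("TA", 1, T1 = 1420, T2 = 32, T2star = 27,
#'             fat_fraction = 0.04, trate = 71.09)
#' @export
tissue_spec <- function(name, label_id, T1, T2, T2star,
                        fat_fraction = 0, trate = 0, M0 = 1000) {
  stopifnot(is.character(name), length(name) == 1L)
  label_id <- as.integer(label_id)
  if (is.na(label_id) || label_id < 0L ||
      (label_id == 0L && name != "background"))
    stop("label_id must be a positive integer (0 is reserved for 'background')")
  if (!all(is.finite(c(T1, T2, T2star, M0))) ||
      T1 <= 0 || T2 <= 0 || T2star <= 0 || M0 <= 0)
    stop("T1, T2, T2star and M0 must be positive and finite")
  if (!(T2star <= T2 && T2 <= T1))
    stop("relaxation times must satisfy T2* <= T2 <= T1")
  if (fat_fraction < 0 || fat_fraction > 1)
    stop("fat_fraction must lie in [0, 1]")
  if (trate < 0) stop("trate must be >= 0")
  structure(list(name = name, label_id = label_id,
                 T1 = T1, T2 = T2, T2star = T2star,
                 fat_fraction = fat_fraction, trate = trate, M0 = M0),
            class = "tissue_spec")
}

#' Default tissue sets for healthy and disease-affected calf muscle
#'
#' Per-muscle TRATE defaults are the cohort means reported for healthy
#' controls and for ALS patients; baseline relaxation times are typical
#' 3 T skeletal-muscle values. Relative to healthy muscle, the diseased
#' set carries lower TRATE, higher fat fraction (about +39% on average)
#' and longer T2 (about +18%), matching the group-level contrasts the
#' analysis is designed to detect.
#'
#' @param condition `"healthy"` or `"als"`.
#' @param background Include a zero-label background compartment with
#'   near-zero signal.
#' @return List of [tissue_spec()] objects (TA, PL, TP, MG, LG, and
#'   optionally background).
#' @export
calf_tissues <- function(condition = c("healthy", "als"), background = TRUE) {
  condition <- match.arg(condition)
  base <- list(
    #        name  id  T1    T2    T2*   ff_h  trate_h trate_a
    list("TA", 1L, 1420, 32.0, 27.0, 0.040, 71.09, 27.67),
    list("PL", 2L, 1400, 33.0, 26.0, 0.050, 80.50, 52.75),
    list("TP", 3L, 1430, 31.0, 25.0, 0.045, 83.80, 43.94),
    list("MG", 4L, 1410, 34.0, 28.0, 0.055, 89.56, 58.72),
    list("LG", 5L, 1415, 33.5, 27.5, 0.050, 85.81, 50.39))
  tissues <- lapply(base, function(b) {
    ff <- if (condition == "als") min(1, b[[6]] * 1.39) else b[[6]]
    t2 <- if (condition == "als") b[[4]] * 1.18 else b[[4]]
    tissue_spec(b[[1]], b[[2]], T1 = b[[3]], T2 = t2, T2star = b[[5]],
                fat_fraction = ff,
                trate = if (condition == "als") b[[8]] else b[[7]])
  })
  if (background)
    tissues <- c(tissues, list(tissue_spec("background", 0L,
                                           T1 = 500, T2 = 50, T2star = 20,
                                           fat_fraction = 0, trate = 0,
                                           M0 = 1e-3)))
  tissues
}

#' Contrast-agent wash-in kinetics
#'
#' Mono-exponential wash-in to an equilibrium plateau: the tissue
#' concentration is zero before the arrival time and
#' `Ct(t) = C_eq * (1 - exp(-k_washin * (t - t_arrival)))` afterwards.
#' No washout is modelled; the analysis only needs a well-defined
#' equilibrium window at the end of the dynamic series.
#'
#' @param t_arrival Contrast arrival time in seconds (default 90 s, i.e.
#'   after the pre-injection baseline of the dynamic scan).
#' @param C_eq Equilibrium plateau concentration in mM.
#' @param k_washin Wash-in rate constant in s^-1 (> 0). The default 0.02
#'   puts the last 10 of 150 dynamic frames (frame spacing 5.2 s) firmly
#'   on the plateau.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(t_arrival = 90, C_eq = 0.08, k_washin = 0.02) {
  if (t_arrival < 0) stop("t_arrival must be >= 0")
  if (C_eq < 0) stop("C_eq must be >= 0")
  if (k_washin <= 0) stop("k_washin must be > 0")
  structure(list(t_arrival = t_arrival, C_eq = C_eq, k_washin = k_washin),
            class = "kinetic_model")
}

#' Gadolinium-based contrast agent
#'
#' Only the longitudinal relaxivity r1 enters the analysis (Ct = dR1/r1).
#' The default 4.5 L mmol^-1 s^-1 is a typical value for a macrocyclic
#' gadolinium agent in tissue at 3 T; the same value must be used in the
#' forward simulation and the inverse analysis, which makes downstream
#' TRATE conclusions independent of the exact number.
#'
#' @param r1 Longitudinal relaxivity, L mmol^-1 s^-1 (> 0).
#' @param name Agent name (metadata only).
#' @return An object of class `contrast_agent`.
#' @export
contrast_agent <- function(r1 = 4.5, name = "synthetic-gadolinium") {
  if (!is.finite(r1) || r1 <= 0) stop("r1 must be > 0")
  structure(list(r1 = r1, name = name), class = "contrast_agent")
}

#' MR acquisition protocol
#'
#' Describes one pulse sequence of the exam. `sequence_kind` selects the
#' forward signal model used by [simulate_acquisition()].
#'
#' @param sequence_kind One of `"spgr_vfa"`, `"dual_echo_dynamic"`,
#'   `"multi_echo_gre"`, `"multi_echo_se"`, `"dixon_pair"`.
#' @param TR Repetition time, ms.
#' @param TE_list Echo times, ms, strictly increasing; exactly 2 entries
#'   for `dual_echo_dynamic`.
#' @param flip_angles Flip angles in degrees (several for `spgr_vfa`).
#' @param n_dynamics Number of dynamic frames (dynamic protocol only).
#' @param dt_dynamic Time per dynamic frame, seconds. The default 5.2 s
#'   corresponds to 150 frames in a 12:55 dynamic scan.
#' @return An object of class `mr_protocol`.
#' @export
mr_protocol <- function(sequence_kind, TR, TE_list, flip_angles,
                        n_dynamics = NULL, dt_dynamic = NULL) {
  kinds <- c("spgr_vfa", "dual_echo_dynamic", "multi_echo_gre",
             "multi_echo_se", "dixon_pair")
  sequence_kind <- match.arg(sequence_kind, kinds)
  if (TR <= 0 || any(TE_list <= 0) || any(flip_angles <= 0))
    stop("all timings and flip angles must be > 0")
  if (length(TE_list) > 1 && any(diff(TE_list) <= 0))
    stop("TE_list must be strictly increasing")
  if (sequence_kind == "dual_echo_dynamic") {
    if (length(TE_list) != 2L) stop("dual_echo_dynamic needs exactly 2 echoes")
    if (is.null(n_dynamics) || is.null(dt_dynamic) ||
        n_dynamics < 2 || dt_dynamic <= 0)
      stop("dual_echo_dynamic needs n_dynamics >= 2 and dt_dynamic > 0")
  }
  structure(list(sequence_kind = sequence_kind, TR = TR,
                 TE_list = TE_list, flip_angles = flip_angles,
                 n_dynamics = n_dynamics, dt_dynamic = dt_dynamic),
            class = "mr_protocol")
}

#' Default exam protocols
#'
#' The five quantitative protocols of the exam with their acquisition
#' parameters: a dual-echo dynamic gradient-echo time series (TR 21 ms,
#' TE 1.06/20.0 ms, flip 25 deg, 150 dynamics at 5.2 s), a multi-echo GRE
#' for T2* (TR 34 ms, 5 echoes 4.9-30.9 ms), a variable-flip-angle SPGR
#' for T1 (TR 7.7 ms, TE 4.6 ms, flips 20..2 deg), a two-point Dixon pair
#' (TR 8.5 ms, flip 3 deg), and a multi-echo spin echo for T2 (6 echoes
#' 12.0-42.5 ms).
#'
#' @return Named list of [mr_protocol()] objects:
#'   `dynamic`, `megre`, `vfa`, `dixon`, `mese`.
#' @export
default_protocols <- function() {
  list(
    dynamic = mr_protocol("dual_echo_dynamic", TR = 21,
                          TE_list = c(1.06, 20.0), flip_angles = 25,
                          n_dynamics = 150, dt_dynamic = 5.2),
    megre = mr_protocol("multi_echo_gre", TR = 34,
                        TE_list = c(4.9, 11.4, 17.9, 24.4, 30.9),
                        flip_angles = 25),
    vfa = mr_protocol("spgr_vfa", TR = 7.7, TE_list = 4.6,
                      flip_angles = c(20, 18, 16, 14, 12, 10, 8, 6, 4, 2)),
    dixon = mr_protocol("dixon_pair", TR = 8.5, TE_list = 1.4,
                        flip_angles = 3),
    mese = mr_protocol("multi_echo_se", TR = 3605,
                       TE_list = c(12.0, 18.1, 24.2, 30.3, 36.4, 42.5),
                       flip_angles = 90))
}
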