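---
title: "Relaxivity contrast imaging of muscle: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxivity contrast imaging of muscle: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcitrate)
```

This vignette documents the physical models behind `rcitrate`, the
parameters that matter, the synthetic-data generator the package is
validated against, and the places where the design was genuinely open
and a choice had to be made.

## Signal models

**Spoiled gradient echo (SPGR).** All gradient-echo protocols use the
steady-state magnitude signal

$$S = M_0 \sin\alpha \,\frac{1 - E_1}{1 - E_1\cos\alpha}\, e^{-TE/T_2^*},
\qquad E_1 = e^{-TR/T_1},$$

with $TR, TE$ in ms and $\alpha$ the flip angle. `spgr_signal()` is
this closed form; the variable-flip-angle (VFA) T1 fit and the dynamic
inversion are its inverses. The multi-echo spin echo uses pure
mono-exponential decay $S(TE) = M_0 e^{-TE/T_2}$, and the two-point
Dixon pair emits in-phase $W+F$ and opposed-phase $|W-F|$ magnitudes
with $F = \mathrm{FF}\cdot M_0$.

**Dynamic forward model.** During contrast passage the relaxation
rates become time-varying and linear in the tissue concentration
$C_t(t)$ (in mM):

$$R_1(t) = \tfrac{1}{T_{1,0}} + r_1\,C_t(t), \qquad
  R_2^*(t) = \tfrac{1}{T_{2,0}^*} + \mathrm{TRATE}\cdot C_t(t).$$

The linear $R_2^*$ term is the quantity of interest: its slope with
respect to concentration — the transverse relaxivity at tracer
equilibrium — reflects how the agent is compartmentalized around
myofibers, not merely how much of it is present. Each frame of the
dual-echo series evaluates the SPGR equation at both echo times with
these rates.

**Inverse chain.** Per ROI (or voxel):

1. $R_2^*(t) = \ln(S_1/S_2)/(TE_2-TE_1)$, and
   $\Delta R_2^*(t)$ subtracts the baseline-window mean;
2. the echoes are extrapolated to $TE=0$,
   $S_0 = S_1 e^{TE_1 R_2^*}$, removing $T_2^*$ decay;
3. $M_0$ is self-calibrated from the baseline mean of $S_0$ together
   with the pre-contrast T1 (from the VFA fit), each frame is inverted
   for $E_1$ and hence $R_1(t)$, giving
   $\Delta R_1(t) = R_1(t) - 1/T_{1,\mathrm{base}}$;
4. $C_t(t) = \Delta R_1(t)/r_1$;
5. $\mathrm{TRATE} = \Delta R_2^* / C_t$ over the equilibrium window.

The self-calibration in step 3 makes every curve, and TRATE itself,
invariant to a global receiver gain; the division in step 5 makes
TRATE invariant to the injected dose in this linear forward model.
Both invariances are asserted in the test suite.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| dynamic TR / TE₁, TE₂ / flip | 21 / 1.06, 20.0 / 25° | ms, deg | dual-echo dynamic protocol of the exam |
| dynamics × frame time | 150 × 5.2 | s | 12:55 dynamic scan; ~17 baseline frames |
| injection time | 90 | s | pre-injection baseline duration |
| VFA flips / TR / TE | 20…2° / 7.7 / 4.6 | deg, ms | T1-mapping protocol |
| equilibrium window | last 10 frames | frames | tracer-equilibrium definition |
| baseline window | frames before injection − 1 guard | frames | guard against partial-arrival contamination |
| r1 | 4.5 | L mmol⁻¹ s⁻¹ | typical macrocyclic gadolinium agent at 3 T; unstated for the real agent, so a config value used identically in forward and inverse direction — TRATE conclusions do not depend on it |
| `ct_floor` | 0.01 | mM | guards the TRATE quotient as $C_t \to 0$; below it the fit reports "no contrast arrival" rather than a diverging ratio |
| `qc_max_flagged` | 0.2 | — | fraction of flagged window points above which QC fails; negative ΔR2*/Ct points are kept (not clamped) but counted |
| wash-in rate `k_washin` | 0.02 | s⁻¹ | ~50 s time constant; places the last 10 of 150 frames on the plateau to < 0.01% |
| plateau `C_eq` | 0.08 / 0.11 | mM | healthy / affected equilibrium concentration operating points |

## The phantom: what it emulates, what it does not

`build_phantom()` draws five connected muscle sectors (TA, PL anterior;
TP, MG, LG posterior) inside a circular leg cross-section, each with
piecewise-constant ground truth; `calf_tissues()` provides per-muscle
defaults. Healthy-control TRATE defaults are the per-muscle cohort
means (71.09, 80.50, 83.80, 89.56, 85.81 mM⁻¹ s⁻¹; TA, PL, TP, MG,
LG), the disease-affected set the corresponding (27.67, 52.75, 43.94,
58.72, 50.39). Relative to healthy tissue the affected set also
carries a 39% higher fat fraction and 18% longer T2 — the group-level
contrasts the cohort statistics are designed to detect. Baseline
relaxation times are typical 3 T skeletal-muscle values (T1 ≈ 1.4 s,
T2 ≈ 31–34 ms, T2* ≈ 25–28 ms).

Kinetics are a mono-exponential wash-in to a plateau with no washout:
the analysis only requires a well-defined equilibrium window, so a
more elaborate pharmacokinetic model would add parameters without
adding testable structure. Noise is Rician — Gaussian on the two
quadrature channels, magnitude taken — so the zero-signal Rayleigh
floor and low-SNR bias are representable; no Gaussian approximation is
made.

Deliberately **not** modelled: B0/B1 field inhomogeneity, slice
profiles, stimulated echoes in the turbo spin echo, partial-volume
mixing at muscle boundaries, subject motion, coupled fat–water
dynamics (fat appears only in the Dixon pair), and contrast washout.
Consequently, passing tests demonstrate correctness of the estimator
chain and its noise behaviour — not robustness to the confounds above,
which in real data are handled by acquisition and registration
choices outside this package's scope. The within-muscle disease effect
is uniform by default: nothing in the source material constrains its
spatial distribution, so the phantom defaults to the simplest
assumption and exposes a smooth multiplicative variation field
(`variation_amp`) as configuration instead.

## Numerical choices and degenerate inputs

- **VFA fit**: ordinary least squares on the linearized form
  $S/\sin\alpha$ vs $S/\tan\alpha$; slope outside $(0,1)$, all-zero
  signals, or T1 outside (1, 10000) ms ⇒ voxel masked (`NA`), never
  clamped; masked counts are reported. T1 is scale-invariant, and the
  returned $M_0$ absorbs the fixed $e^{-TE/T_2^*}$ factor.
- **Mono-exponential decay**: signal-weighted log-linear least squares
  (weights $S^2$, de-biasing the log transform); a Gauss–Newton
  nonlinear option (`method = "nls"`) exists and serves as the test
  oracle. Two echoes reduce exactly to
  $(\ln S_1 - \ln S_2)/(TE_2 - TE_1)$.
- **Dixon**: $\mathrm{FF} = (IP - OP)/(2\,IP)$ clipped to $[0,1]$,
  background masked where $IP$ falls below 5% of its 99th percentile.
  Water dominance is assumed; no swap resolution.
- **Dynamic inversion**: frames where the $E_1$ inversion leaves
  $(0,1)$ (e.g. a noise spike above the calibrated ceiling) are
  flagged `NA` and excluded from window means; the QC verdict records
  the flagged fraction. Non-positive echo signals are flagged at the
  $R_2^*$ stage the same way.
- **TRATE**: the default is the *ratio of window means*, which is less
  noise-biased than averaging pointwise quotients; `mean_of_ratios` is
  retained and the two are compared in tests (they agree to < 0.5% on
  a plateau at SNR 50).
- **Normality tests**: Lilliefors and Anderson–Darling statistics are
  computed in-package and referred to a seeded Monte-Carlo null
  simulated at the sample's own $n$ (cached per size). This is exact
  in expectation at any $n \ge 4$, avoids approximation tables, and
  keeps both tests on the same footing; a zero-variance sample is a
  reported failure, not an error.

## Open design decisions

- **ROI curves vs voxelwise TRATE.** Whether TRATE should be computed
  from ROI-mean signal curves or voxelwise-then-averaged is genuinely
  ambiguous; both are implemented (`roi_mode`). The default is
  ROI-curve-first for SNR; voxelwise maps remain available for
  figures. On noise-free uniform tissue the two agree exactly.
- **TE-extrapolated vs first-echo signal for ΔR1.** The package
  extrapolates to $TE = 0$ before the $T_1$ inversion as the
  physically consistent choice: otherwise the concentration estimate
  inherits a $T_2^*$-dependent bias exactly where ΔR2* is largest.
- **Welch vs paired comparison.** Cohorts of 12 and 11 independent
  subjects cannot be paired, so the cohort default is Welch's
  two-sample t-test; paired mode exists for within-subject visit
  contrasts and refuses unequal lengths with an explicit message.
- **Confidence intervals** are t-based on subject-level means. No
  multiple-testing correction is applied to the five per-muscle
  p-values (a Bonferroni column is emitted for transparency only).
- **Two-point Dixon** is the package's self-contained computable
  definition of fat fraction; it is a documented substitute for
  vendor multi-echo reconstructions, not a replica of them.

## Problem sizes

The test suite runs on small grids chosen to exercise every code path
with comfortable margins: 12×12×2 to 32×32×2 phantoms (a full 64×64×8
geometry test included), the full 150-frame dynamic protocol, 100-seed
Monte-Carlo recovery at SNR 50 over a >200-voxel ROI, 1000-replicate
cohort simulations and 4000-replicate type-I calibration. The whole
suite completes in well under a minute on one core; the acceptance
script in seconds.

## Known limitations

- The phantom's geometry is a stylized cross-section; it validates
  estimators, not segmentation or registration.
- TRATE here assumes the linear relaxivity regime; exchange and
  leakage corrections, arterial input functions and perfusion
  parameters are out of scope.
- Group-separation simulations treat subjects as independent draws
  from per-muscle normals; real cohorts have within-subject
  correlation across muscles that such simulations neither need nor
  reproduce.
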