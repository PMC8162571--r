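# rcitrate

Relaxivity contrast imaging (RCI) of skeletal muscle in R: a digital
calf phantom, baseline relaxometry, and estimation of the **transverse
relaxivity at tracer equilibrium (TRATE)** from dual-echo dynamic
contrast-enhanced MRI, with the cohort and longitudinal statistics used
to compare diseased and healthy muscle.

## The problem and the method

Neuromuscular diseases such as ALS degrade the architecture of muscle
myofibers (fiber diameter, density, organization) before gross changes
such as fatty infiltration or edema become prominent. When a
gadolinium-based contrast agent equilibrates in the extracellular space
around myofibers, the magnetic field perturbations it induces — and
hence the change in the effective transverse relaxation rate — depend
on the geometry of those compartments. RCI exploits this: during and
after contrast injection, a dual-echo dynamic gradient-echo series
simultaneously tracks

- the transverse rate change, per voxel/ROI and time point
  `ΔR2*(t) = R2*(t) − R2*(baseline)`, with
  `R2*(t) = ln(S1/S2)/(TE2 − TE1)` from the two echoes, and
- the longitudinal rate change `ΔR1(t)`, obtained by extrapolating the
  two echoes to TE = 0 and inverting the spoiled gradient-echo signal
  equation against the pre-contrast T1 map, which yields the tissue
  contrast-agent concentration `Ct(t) = ΔR1(t)/r1`.

The core parameter is the quotient of the two at tracer equilibrium
(the last frames of the dynamic series):

```
TRATE = ΔR2* / Ct   [mM⁻¹ s⁻¹]  at contrast-agent equilibrium
```

TRATE is sensitive to myofiber microstructure and falls substantially
in denervated, atrophying muscle, while concentration uptake itself
changes little. The package implements the full chain — forward
simulation, variable-flip-angle T1 mapping, mono-exponential T2/T2*
mapping, two-point Dixon fat fraction, ΔR2*/ΔR1/Ct/TRATE estimation,
and per-muscle cohort statistics (Welch/paired t-tests, Monte-Carlo
Lilliefors and Anderson–Darling normality checks, percent differences
and %/month longitudinal rates).

Because real patient volumes are not redistributable, the package
ships a **digital calf phantom**: five labelled muscle ROIs (TA, PL,
TP, MG, LG) on a voxel grid with per-tissue ground truth (T1, T2, T2*,
fat fraction, TRATE), a 90 s pre-injection baseline followed by
mono-exponential contrast wash-in to an equilibrium plateau, the
acquisition parameters of the five-protocol exam, and Rician magnitude
noise. Every estimator is validated against this generator, from exact
noise-free round trips to Monte-Carlo recovery at realistic SNR.

## Worked example

Simulate a disease-affected calf exam and estimate TRATE per muscle:

```r
library(rcitrate)

tissues   <- calf_tissues("als")                 # per-muscle ground truth
phantom   <- build_phantom(tissues, grid_shape = c(32, 32, 4), geometry_seed = 1)
protocols <- default_protocols()

kin <- kinetic_model(t_arrival = 90, C_eq = 0.11, k_washin = 0.02)
dyn <- simulate_acquisition(phantom, protocols$dynamic, kinetics = kin,
                            noise_sd = 2, seed = 2)
vfa <- simulate_acquisition(phantom, protocols$vfa, noise_sd = 2, seed = 3)

t1map <- fit_vfa_t1(vfa$data, protocols$vfa$flip_angles, protocols$vfa$TR)
fit   <- rci_fit(dyn, t1map$T1, labels = phantom$labels)
fit
#> Relaxivity contrast fit (roi_curve_first, ratio_of_means)
#>   baseline: 17 frames; equilibrium: last 10 frames
#>  roi trate dr2star_eq  ct_eq voxel_count qc_pass
#>    1 28.77      3.125 0.1086         492    TRUE
#>    2 54.29      5.868 0.1081         536    TRUE
#>    3 45.91      4.946 0.1077         532    TRUE
#>    4 60.65      6.518 0.1075         556    TRUE
#>    5 51.94      5.570 0.1072         476    TRUE
```

Reading the output: each row is one muscle ROI (1 = tibialis anterior
… 5 = lateral gastrocnemius). `ct_eq` is the estimated equilibrium
contrast concentration (here ≈ 0.11 mM, the simulated plateau),
`dr2star_eq` the equilibrium ΔR2* in s⁻¹, and `trate` their quotient —
within a few percent of the generating ground truth (27.67, 52.75,
43.94, 58.72, 50.39 mM⁻¹ s⁻¹) at this noise level. `coef(fit)` returns
the TRATE vector, `summary(fit)` adds window SDs and QC flags, and
`plot(fit)` draws the Ct(t) and ΔR2*(t) curves with the baseline and
equilibrium windows shaded.

`run_pipeline(default_scene(), output_dir)` runs the whole chain for a
small two-cohort study (simulate → fit maps → TRATE → cohort tables)
and writes per-subject CSVs, per-metric comparison tables (CSV and
Markdown) and a JSON manifest with config, seed, timings and QC
counters.

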