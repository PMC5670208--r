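# cb1quant

Quantification pipeline for multimodal pharmacological imaging studies of
the cannabinoid-1 (CB1) receptor system: PET kinetic quantification of
receptor availability, rule-based skin-conductance scoring, symptom
time-course statistics, a permutation-based BOLD effect estimator, and the
correlation stage that ties receptor availability to drug effects. A
synthetic-data module generates every input the pipeline consumes, so the
whole chain is testable end to end without any subject data.

## Who this is for

Researchers analysing drug-challenge designs in which baseline receptor
availability (PET with an arterial input function), symptom ratings over a
few hours, electrodermal arousal during a task, and task fMRI are combined,
and the question is whether the magnitude of a drug's behavioural and
neural effects tracks regional receptor availability.

## The quantitative core

**Volume of distribution by spectral analysis.** A regional PET
time-activity curve C_T(t) is modelled as a non-negative sum of
convolutions of the metabolite-corrected arterial plasma input function
C_p(t) with decaying exponentials,

    C_T(t) = (1 − V_b) · Σ_j α_j (C_p ⊗ e^(−β_j t)) + V_b · C_b(t),
    α_j ≥ 0,  0 ≤ V_b ≤ 1,

on a log-spaced frequency grid β_j ∈ [0.00063, 0.1] s⁻¹. The slow bound
sits just above the ¹¹C decay constant ln 2 / (20.4 · 60) = 0.0005663 s⁻¹
(log₁₀ = −3.25): nothing in tissue can appear slower than the physical
decay of the label. The weighted problem (frame weights w_i = L_i/T_i from
frame length and trues rate) is solved by non-negative least squares, and

    V_T = Σ_j α_j / β_j          (ml/g, unit tissue density),
    IRF(60 min) = Σ_j α_j e^(−3600 β_j).

**Input function.** Continuous whole-blood counts (0–15 min) are converted
to plasma with a four-parameter sigmoid fitted to the plasma/blood ratio of
the first six discrete samples (3–30 min), merged with the late discrete
plasma samples (20–75/90 min), multiplied by a sigmoid fit of the parent
fraction, and shifted by a grid-searched arrival delay.

**SCR scoring.** A fluctuation is a rise of ≥ 0.01 µS whose first rising
sample falls 0.5–3 s after the stimulus; amplitude is onset-to-peak,
latency is onset-to-stimulus.

**Symptom statistics.** Trapezoidal AUC of ratings versus time, Friedman
tests for drug/placebo comparisons (with an exact permutation mode),
Kolmogorov–Smirnov normality checks, and 1–2 h window means.

**BOLD effect.** The event design is convolved with two gamma-variate
kernels (4 s and 8 s peaks); the voxel statistic is the sum-of-squares
ratio (model SS / residual SS) with circular-shift permutation p-values,
and group inference uses voxelwise medians with sign-flip cluster-mass
permutation calibrated so the expected false-positive cluster count per
volume stays below one.

**Association.** Pearson correlations of regional V_T with the
drug-induced anxiety change (1–2 h window mean, drug − placebo) and the
amygdala SSQ effect, plus post-hoc checks, without cross-hypothesis
multiplicity correction.

## Worked example

```r
library(cb1quant)

blood <- gen_blood_dataset(seed = 1)
input <- apply_parent_correction(
  build_plasma_curve(blood, fit_plasma_ratio(blood)),
  fit_parent_fraction(blood))

sch <- meppep_frame_schedule()        # 35 frames, 95 min
kp  <- kinetic_params("two_tissue", K1 = 0.4, k2 = 0.2,
                      k3 = 0.05, k4 = 0.1, vb = 0.05)   # analytic VT = 3
tac <- gen_tissue_tac(input, kp, sch, noise_scale = 1, seed = 2)
fit <- fit_spectral(tac, build_basis(input, sch),
                    weights = frame_weights(tac))
fit
#> spectral_fit
#>   VT = 3.006 ml/g, Vb = 0.044, IRF(60 min) = 3.422e-05 1/s
#>   100 basis frequencies in [0.00063, 0.1] 1/s, 5 non-zero, weighted rss 39.91
```

The estimated V_T (3.006 ml/g) recovers the analytic ground truth (3 ml/g)
to 0.2% at a realistic noise level, the blood-volume fraction (0.044) is
close to the simulated 0.05, and the near-zero IRF at 60 min reflects the
slow kinetics. The correlation stage on a 14-subject synthetic cohort:

```r
co <- gen_cohort(cohort_spec(anxiety_effect_corr = 0.47,
                             ssq_effect_corr = 0.53, seed = 14))
run_association(co)
#> Association report (no cross-hypothesis multiplicity correction)
#>                           hypothesis     role  n      r      p_two_sided
#>    anxiety_delta ~ vt_right_amygdala  primary 14  0.475       0.0859
#>       ssq_effect ~ vt_right_amygdala  primary 14  0.538       0.0471
#>  psychosis_delta ~ vt_right_amygdala post-hoc 14 -0.079       0.789
#>    scr_fear_count_delta ~ ssq_effect post-hoc 14 -0.113       0.701
```

Sample correlations at n = 14 scatter widely around the generating values
(0.47 and 0.53 here); the report always prints n alongside r and both
one- and two-sided p-values.

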