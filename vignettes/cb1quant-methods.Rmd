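---
title: "Methods: PET spectral quantification, electrodermal scoring and permutation BOLD statistics"
author: "cb1quant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET spectral quantification, electrodermal scoring and permutation BOLD statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cb1quant)
```

This vignette is the package's own account of its models and numerical
choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The study design the package serves

The pipeline targets a within-subject pharmacological imaging design: a
small cohort (fourteen subjects in the emulated study) receives drug and
placebo one month apart in a double-blind crossover, with symptom ratings
at 0, 1, 2 and 3 h, task fMRI and skin conductance acquired between 1 and
2 h, and — on a separate occasion — a dynamic PET scan with arterial blood
sampling quantifying baseline CB1 receptor availability. The scientific
question is correlational: does the size of the drug's anxiety and
amygdala-activation effects track regional receptor availability (V~T~)?
Because subject-level data of that kind are not publicly distributable,
the package pairs every analysis stage with a generator that produces
inputs with the statistical structure the stage assumes, which is what
makes the pipeline testable end to end.

## Input function construction

Arterial blood enters in two forms: a continuous whole-blood detector
record over the first 15 min at 1 s resolution, and discrete samples at 3,
5, 10, 15, 20, 30, 50 and 75 min (a 90-min sample measures plasma and
whole blood only; the parent fraction cannot be assayed there and the
sample is excluded from the parent fit but merged into the plasma curve
when supplied).

The plasma-to-blood ratio from the first six samples, and the parent
fraction from all assayed samples, are each fitted with a four-parameter
logistic `a + (b − a)/(1 + (t/c)^d)`. The optimiser is Levenberg–Marquardt
with a small multi-start grid over the half-point `c` (quartiles of the
sample times) and steepness `d` (0.5–8), keeping the best residual sum of
squares; this makes the fit insensitive to point ordering and start
choice. Convergence is accepted at relative tolerances of 1e−12; a fit
that fails from every start is an error by default.

Continuous plasma is whole blood times the fitted ratio on [0, 15 min];
the late discrete plasma points (20, 30, 50, 60, 75, 90 min — whichever
exist; absent ones are logged) are merged onto one strictly increasing
grid with piecewise-linear interpolation between breakpoints, the simplest
choice given ~10-min gaps between late samples. The input must cover the
full 95-min scan although the last sample is at 75 (or 90) min: beyond the
last breakpoint the curve is extended by a single-exponential (log-linear)
fit to the last three points, the standard washout assumption. The parent
correction is a pointwise product with the parent sigmoid clipped to
[0, 1].

**Arrival delay.** The bolus reaches the brain and the peripheral sampling
site at slightly different times. The delay is estimated by grid search
(−30 to +30 s, 0.5 s steps by default): each candidate shift is applied to
the input and the whole-brain TAC is refitted by spectral analysis; the
shift minimising the weighted residual wins and is then fixed for the
entire brain. Which residual the estimate should minimise is a genuinely
open choice; the package uses the spectral-fit residual and records the
choice in its output metadata. The search uses a reduced basis (40
frequencies) and a fixed zero blood-volume, since only relative fit
quality across shifts matters; a boundary optimum or an essentially flat
objective (relative range < 0.1%) is signalled as a warning.

## Spectral quantification of V~T~

The tissue model is a non-negative mixture of input-function convolutions
with decaying exponentials plus a vascular term:

$$C_T(t) = (1 - V_b)\sum_j \alpha_j \,(C_p \otimes e^{-\beta_j t}) + V_b\, C_b(t),
\qquad \alpha_j \ge 0,\ 0 \le V_b \le 1.$$

Whether the `(1 − V_b)` factor should multiply the tissue term is not
universally standardised; the package applies it, and uses the same
observation model in the TAC generator, so estimator and generator share
one convention.

* **Frequency grid.** 100 log-spaced β between 0.00063 and 0.1 s⁻¹. The
  slow bound is 10^(−3.2), chosen just above the ¹¹C decay constant
  0.0005663 s⁻¹ (= ln 2 / 1224 s, log₁₀ −3.25): the slowest kinetic a
  decay-corrected tissue curve can legitimately express corresponds to the
  physical decay of the isotope. Only the bounds are fixed by the
  acquisition physics; 100 points make the grid-discretisation error in
  V~T~ far below the 1% recovery tolerance the tests enforce.
* **Basis.** Each column is the convolution evaluated exactly for a
  piecewise-linear input on a 1-s internal grid (the per-step segment
  integral has a closed form and the recursion runs in C via
  `stats::filter`), then averaged over each acquisition frame by the
  trapezoid rule. The β → 0 limit reduces analytically to the running
  integral of the input, which is tested.
* **Weights.** w_i = L_i/T_i (frame length over trues rate), i.e.
  reciprocal variance under count statistics. A zero-trues frame gets
  weight 0 with a warning rather than an infinite variance.
* **Solver.** Weighted NNLS (Lawson–Hanson via `pracma::lsqnonneg`) at
  each candidate V_b: a coarse grid (step 0.05) followed by golden-section
  refinement, tolerance 1e−4 on V_b. The tests cross-check the solver
  against a brute-force active-set quadratic program (exhaustive support
  enumeration with KKT verification) to 1e−6.
* **Summaries.** V~T~ = Σ α_j/β_j, reported in ml/g under unit tissue
  density (the conversion from ml/cm³ is a documented assumption), and the
  impulse response at 60 min, Σ α_j e^(−3600 β_j), a stability metric for
  slowly equilibrating tracers.
* **Rank-shaping regularisation.** The variance-control filter for slow
  tracers is implemented as an optional mass-preserving Gaussian smoothing
  of the coefficient spectrum along the log-β grid (width 2 grid steps by
  default). `regularisation = "none"` reproduces plain spectral analysis
  exactly and is the default; all recovery guarantees are stated for the
  plain estimator, with a test confirming shaping does not destroy V~T~
  recovery.
* **Parcellation.** `roi_mean_tac()` is an unweighted mean over the voxels
  of an integer label map, per frame. Whether a vascular-corrected or raw
  V~T~ map should be parcellated is left to the caller: the fit reports
  both V~T~ (from the tissue spectrum) and V_b.

**TAC generator.** `gen_tissue_tac()` convolves the input with the
analytic one- or two-tissue impulse response (closed-form exponential
mixtures; V~T~ = K₁/k₂ or (K₁/k₂)(1 + k₃/k₄)) on a 0.5-s grid — finer
than, and numerically distinct from, the estimator's basis grid — and adds
zero-mean Gaussian noise with per-frame variance proportional to T_i/L_i,
the reciprocal of the statistical weight. When the schedule has no
measured trues, the generator synthesises them as decay-weighted frame
activity, so relative noise grows late in the scan as counts decay. A
noise scale of 1 yields ~4% coefficient of variation at the TAC peak,
which is what the package treats as a realistic regional noise level; the
acceptance checks use 200 replicates per level at scales 0.5–4.

## Electrodermal scoring

A fluctuation is scored per stimulus: baseline is the mean conductance
over the 1 s before stimulus onset (the width is a config key; the rule
itself names no width); a candidate rise opens at the first sample whose
smoothed slope exceeds 0.005 µS/s (a 0.25-s causal moving average
suppresses sensor noise, and a slope floor keeps slow tonic drift from
anchoring onsets at the window edge); the onset is walked back to the
first genuinely rising raw sample so the smoothing window introduces no
latency lag. An event is recorded iff the onset falls 0.5–3 s
post-stimulus and the onset-to-peak rise is at least 0.01 µS; at most one
event — the first qualifying rise — is scored per stimulus. The window
anchor (onset versus peak) is a config option with onset as default, since
the printed rule is ambiguous on this point.

Two readings of the 0.01-µS criterion exist: onset-to-peak (trough-to-peak
convention) or peak-above-pre-stimulus-baseline. With overlapping
responses (mean inter-stimulus intervals of ~6–8 s against a ~2-s decay
constant), a preceding response's decay can hold the pre-stimulus mean
above a genuine later fluctuation, so the baseline-referenced reading
destroys recall on events that plainly satisfy the trough-to-peak rule.
The package defaults to onset-to-peak and exposes the stricter check as
`require_above_baseline`. Rise time is emitted per event but enters no
downstream statistic.

The generator shapes transients as a difference of exponentials (rise
0.75 s, decay 2 s — the shape is a modelling choice, not prescribed),
draws onset latencies uniformly within the scoring window quantised to
the trace sampling grid (an event starting within the last sample of the
window is unresolvable at trace resolution, so truth is kept one sample
inside), and amplitudes lognormally above a 0.02-µS floor with an optional
fearful-versus-neutral offset. The task's printed arithmetic (60
two-second stimuli at mean 5.9-s intervals versus a 6-minute run) does not
close, so stimulus count, interval and duration are all free parameters of
`make_stimulus_table()`.

## Symptom statistics

AUC is the trapezoid rule on the raw ratings by default;
baseline-subtracted AUC is an option (`baseline_subtract`), since which of
the two the original analysis used is not stated. The Friedman test uses
within-subject mid-ranks with the standard tie correction (delegated to
`stats::friedman.test`) and offers an exact conditional-permutation
p-value for small cohorts; whether the drug/placebo comparison should be
run on AUCs or per-timepoint values is likewise exposed (`mode`), AUC
being the default. The normality check is a one-sample Kolmogorov–Smirnov
test against a normal with the sample mean and SD, asymptotic p. No
correction across scales is applied by default (hypotheses are corrected
within, not across); a Bonferroni switch exists.

The ratings generator reproduces the structure that motivates the
non-parametric analysis: placebo series constant per subject (zero
change-from-baseline variance) and drug responses right-skewed across
subjects. Skew comes from a lognormal subject amplitude with σ = 0.25 —
the mildest clearly-skewed choice — because a monotone transform of a
Gaussian attenuates Pearson correlation with the latent VT score by the
analytic factor σ/√(e^σ² − 1) (0.984 at σ = 0.25), and the generator is
required to deliver requested VT–anxiety correlations to ±0.03. Subject
amplitudes peak between 1 and 2 h (profile 0, 0.9, 1.0, 0.45 at 0–3 h), so
the 1–2 h window mean is the natural effect measure. STAI-S is clipped to
[20, 80] and PANSS subscales to instrument bounds.

## BOLD effect and group inference

The event train (optionally with a 2-s boxcar duration; impulse by
default) is convolved with two unit-peak gamma-variate kernels. Peaks of
4 s and 8 s with shape 6 are the package's defaults — the two-kernel idea
fixes neither latency — giving one early and one late response component
whose weighted sum is fitted per voxel by least squares after de-meaning.
The SSQ ratio is model SS over residual SS; it is invariant to offset and
scale of the series, reported at a cap (default 1e6, flagged) when the
residual vanishes, and defined 0 for a constant series. The "constrained"
element of the effects model is implemented as non-negativity of the
fitted response at its peak: when the best fit is everywhere non-positive
the fit collapses to zero, and the constraint is switchable.

Voxel p-values come from circular-shift (default) or block permutation of
the time series, `p = (1 + #{perm ≥ obs})/(n_perm + 1)` — sub-uniform
under the null by construction. The original wavelet-resampling
permutation machinery is deliberately replaced by these desk-scale schemes;
the calibration property (null p-values uniform; KS distance checked over
500 voxels at 500 permutations) is the safeguard for that simplification.

Group inference standardises each subject's difference map by its SD
(absorbing individual residual-noise differences, and logged as such),
takes voxelwise medians — robust to outlier subjects — and calibrates
both thresholds by within-subject sign-flip permutation. The voxel
threshold is the (1 − voxel_p) quantile of permutation medians pooled
across voxels by default: pooling is unbiased for standardised maps (whose
voxel null is exchangeable), whereas a per-voxel threshold at small
permutation counts is biased by each permutation's contribution to its own
threshold; the per-voxel variant remains available for spatially
inhomogeneous noise. Suprathreshold voxels form face-connected clusters
scored by mass (sum of absolute medians). A cluster is significant when
the expected number of equally massive null clusters per volume —
estimated from the pooled permutation cluster masses — falls below
`fp_per_volume`. The operative rule is "fewer than one false-positive
cluster per volume"; the default target is 0.5 because a threshold tuned
to exactly 1 leaves the realised null count sitting on the boundary, and
half the bound keeps it strictly inside with margin. Any value below 1 is
accepted. Coordinates are reported in voxel indices; spatial normalisation
is out of scope.

## Correlation stage

V~T~ against the anxiety change (drug − placebo 1–2 h window means) and
against the cluster-mean SSQ effect are the two primary, hypothesis-driven
tests; V~T~ against the psychotic-symptom change and SSQ effect against
the fear-SCR count change are post-hoc. p-values come from the t
transform of r on n − 2 degrees of freedom. The report prints n, r and
both sidednesses for every row: the study's printed p-values are
consistent with a directional test but do not settle it, so two-sided is
the default and the one-sided column is always present. No multiplicity
correction is applied across the (few, non-independent) hypotheses,
matching the design's stated stance. A numerically perfect correlation is
flagged `at_floor` rather than reported as p = 0.

**Cohort generator.** V~T~ is drawn from a truncated normal (mean 12.57,
SD 3.27, range 7.51–17.75 ml/g — the emulated study's right-amygdala
values) by rejection sampling, which respects both the SD and the printed
range. Outcomes are `ρ·u + √(1 − ρ²)·ε` with `u` the analytically
standardised truncated-normal score, so the generated Pearson correlation
equals the requested ρ exactly; recovery by the association stage at
n = 14 is then limited only by the small-sample bias of r (≈ −0.013 at
ρ = 0.5), well inside the ±0.03 band the tests enforce over 1000
replicates.

## Problem sizes and runtime

The test suite and acceptance script size their simulations to run on one
CPU in a few minutes: 200 noisy TAC replicates at each of four noise
levels for the V~T~ noise response; 20 random instances for the NNLS/QP
cross-check; 500 null voxels at 500 permutations for p-value calibration;
twenty 20³-voxel, 14-subject datasets each for cluster recovery and null
calibration at 100 sign-flip permutations; 1000 cohort replicates for
correlation recovery.

## What the generators do and do not emulate

The generators reproduce the statistical structure each stage relies on:
bolus-shaped blood curves with sigmoid ratio/parent corrections,
compartment-model TACs under the 35-frame 95-min schedule with
weights-model noise, stimulus-locked SCR transients with configurable
response probability, zero-variance placebo and skewed drug ratings, and
jointly correlated V~T~/outcome records. They do not emulate raw PET
sinograms or image reconstruction, scanner dispersion or dead time, motion,
realistic 3-D anatomy or spatially structured fMRI noise, metabolite
chemistry beyond a monotone parent fraction, or floor/ceiling pathologies
of rating scales beyond hard clipping. Passing tests therefore demonstrate
correctness of the estimators under their stated assumptions — not
robustness to every artefact of real acquisitions.

## Known limitations

* The rank-shaping filter is a spectrum-smoothing stand-in parameterised
  by one width; it preserves coefficient mass but not the original
  method's risk calibration.
* The blood-volume search is one-dimensional and assumes a single global
  optimum in V_b; pathological bases could in principle defeat the
  coarse-grid bracket.
* Cluster inference assumes exchangeable standardised maps under the
  pooled threshold default; strongly inhomogeneous noise calls for the
  voxelwise mode and more permutations.
* The exact Friedman mode enumerates all within-subject rearrangements and
  is guarded to ≤ 2²⁰ combinations.
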