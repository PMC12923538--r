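---
title: "Heart-brain coupling under entrainment rTMS: models and methods"
author: "CardioTMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-brain coupling under entrainment rTMS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CardioTMS)
```

# The measurement model

Prefrontal rTMS delivered in fixed cycles — a 5 s train at 10 Hz followed by
an 11 s rest, repeated every 16 s — drives a periodic perturbation of heart
rate through the frontal–vagal axis. If a stimulation site engages that
pathway, instantaneous heart rate acquires a component at the cycle
frequency $f_0 = 1/16\,\mathrm{s} = 0.0625$ Hz. Heart–brain coupling (HBC)
is the power of that component, estimated per block.

The per-block estimator is an exact-frequency projection rather than an FFT
bin. For samples $x_n$ at times $t_n$ inside the half-open block window,

$$P \;=\; \frac{2}{N^2}\,\Bigl|\sum_n (x_n - \bar x)\,
e^{-i 2 \pi f_0 t_n}\Bigr|^2,$$

which returns $A^2/2$ for a pure sinusoid of amplitude $A$ at $f_0$
regardless of how the block grid aligns with the oscillation. Working at the
exact frequency avoids the resolution limit of a 16 s FFT (whose bin width,
1/16 Hz, equals the target frequency itself); the unit test suite verifies
agreement with a $2^{16}$-point zero-padded FFT oracle to $10^{-6}$
relative. The absolute scale of $P$ (bpm²) is arbitrary in the sense that
only relative and ordering statements are scientifically interpreted.

A session consists of 26 abutting 16 s blocks: 8 pre-stimulation rest
blocks, one protocol rest block at 0 %MSO, 15 active trains ramping in
2 %MSO steps to 120% of the resting motor threshold, and 2 post-stimulation
rest blocks. All 26 powers are computed; only the 16 protocol blocks are
retained for modeling, excluding the flanking rest blocks to mitigate edge
effects. The pre-rest powers feed an optional baseline correction
(`baselineCorrect()`), but the models use the raw powers: the Gamma family
requires strict positivity, and subtraction of a session mean would break
it.

# From ECG to heart rate

`detectRPeaks()` is a Pan-Tompkins-style detector (band-pass 5–15 Hz,
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise threshold with 250 ms refractory period, peak refinement on the
band-passed waveform). `cleanRR()` flags RR intervals outside
[0.25, 2.0] s or deviating more than 20% from the running median of five,
and repairs each flagged run by re-interpolating beats between the
untouched bounding beats; recordings with more than 20% flagged intervals
are rejected rather than repaired. `instantaneousHR()` assigns
$60/\mathrm{RR}$ to each RR midpoint and interpolates with a cubic spline
onto a uniform 4 Hz grid (the standard rate for HRV spectral work), holding
edge values constant outside the midpoint span. Cubic interpolation was
chosen over linear/step to limit spectral leakage at $f_0$; `method =
"linear"` is available for sensitivity analyses. These preprocessing
choices are this package's own defaults, stated here because published
pipelines frequently leave them to supplementary material.

# The synthetic entrainment generator

`simulateStudy()` generates ground-truth-known data with the statistical
structure the analysis assumes. Per recording, instantaneous heart rate is

$$r(t) = \underbrace{b + u_p + v_p (s-1) + c_{\mathrm{pain}}\cdot
\mathrm{pain} + w_{\mathrm{block}}}_{\text{tonic level}}
+ \underbrace{A_{LF}\sin(2\pi f_{LF} t + \phi) + A_{HF}\sin(2\pi f_{HF} t +
\psi)}_{\text{HRV}}
+ \underbrace{d \cdot g(\mathrm{target}) \cdot
D(I)\, h(t)}_{\text{entrainment}} + \varepsilon(t),$$

with $D(I) = 1/(1+e^{-k(I - I_{50})})$ a logistic dose-response in intensity
$I$ (%MT), $h(t)$ a boxcar over each train with exponential recovery
(τ = 3 s) during the rest interval, $d = \pm D_{\max}$ setting direction
(deceleration by default), and white noise $\varepsilon$. Beats are emitted
by integral pulse frequency modulation (IPFM): a beat at every integer
crossing of $\int r/60\,dt$ (trapezoid integration, linear crossing
refinement), which conserves beat count to within one beat of the exact
integral.

Defaults encode a healthy-adult cohort of 19 participants by 3 sessions by
7 targets (six active DLPFC sites and one sham): baseline 70 bpm,
$D_{\max} = 3$ bpm reached only at suprathreshold intensities
($I_{50} = 90$ %MT, $k = 0.15$), LF/HF HRV of 1.5/1.0 bpm at 0.1/0.25 Hz,
and per-target gains spanning 0 (sham) to 1 (the lateral site), mirroring
the qualitative pattern that lateral/posterior sites couple most strongly.
Pain scores (0–10, rising with the participant's absolute stimulation
intensity in %MSO) shift heart rate tonically; this is the generator's key
identifying assumption — a tonic confound contributes nothing at
0.0625 Hz after per-block mean removal, so injected entrainment and
pain confound are separable by construction. Real pain responses may well
contain train-locked components; passing tests therefore show correct
recovery under this separation, not that pain confounding is solved in
real data.

Two design points deserve emphasis:

* **Random-effect placement.** Tonic participant/session offsets in bpm
  (the `sdParticipant`, `sdSessionSlope`, `sdBlock` parameters) are removed
  with each block's mean and so cannot create between-participant variance
  in spectral power. The generator therefore adds multiplicative
  per-participant intercept and session-slope effects on the *modulation
  depth* (log-normal, `sdLogAmpParticipant = 0.3`,
  `sdLogAmpSessionSlope = 0.15`). This is what the model's
  `(1 + session | participant)` structure describes on the log-power scale,
  and it leaves sham — whose gain is exactly 0 — without any stable subject
  signal, so sham repeatability is near zero by construction.
* **Determinism.** One study seed; per-recording substreams are derived
  arithmetically from (seed, participant, session, target), so any cell can
  be regenerated independently of iteration order.

What the generator does not emulate: realistic ECG morphology (P/T waves),
respiration beyond a fixed HF sinusoid, non-stationary HRV, arrhythmia, or
train-locked pain responses.

# The mixed-effects models

Block-level HBC power is strictly positive and right-skewed, so both model
variants use a Gamma family with log link:

$$\log \mu = \mathrm{Session} + \mathrm{Target} + f(\mathrm{\%MT}) +
f(\mathrm{Pain}) + f(\mathrm{SideEffects}) +
f_{\mathrm{target}}(\mathrm{\%MT}) + f(\mathrm{\%MT}, \mathrm{Pain}),$$

with random intercept and session slope by participant and a random
intercept by block. Categorical factors use simple contrasts (entries
$(k-1)/k$ and $-1/k$; sham and session 1 as references, intercept at the
grand mean) and continuous predictors are mean-centered within the modeled
rows. The intensity covariate is the %MT label of each block (the physical
%MSO value divided by the session rMT); the protocol rest block enters at
0 %MT.

* The **GLMM variant** keeps continuous terms linear. Default engine is
  `glmmTMB` (maximum likelihood, Laplace-approximated random effects);
  `engine = "bam"` fits the identical structure in mgcv with random effects
  as penalized "re" smooths by fast REML, roughly an order of magnitude
  faster — the difference matters in simulation studies that refit the
  model hundreds of times, and both engines recover the same effect
  ordering.
* The **GAM variant** replaces the linear continuous terms with cubic
  B-spline smooths of basis dimension 5 (penalized by REML), a by-target
  intensity smooth and an intensity-by-pain tensor interaction. The basis
  is deliberately small: 16 distinct intensities per target do not support
  more, and the package reports effective degrees of freedom per smooth
  rather than pretending to a particular penalized-smoother lineage.
  `buildDesign()` exposes the same construction (partition-of-unity cubic
  B-splines, simple contrasts) as plain matrices for inspection and for
  oracle tests.

Coefficients are reported exponentiated (response-ratio scale, 1 = no
effect) with delta-method standard errors; all p-values from a model
summary receive Benjamini–Hochberg FDR adjustment jointly across parametric
and smooth terms. Model comparison is by AIC (`compareModels()`); the
conditional $R^2$ reported is the squared correlation between conditional
fitted values and observations — a descriptive quantity, not a variance
decomposition.

**Marginal contrasts.** `marginalContrasts()` predicts at the population
level (random effects excluded, covariates at their centered means, session
at the grand mean) for each target at requested intensities — 60 %MT,
100 %MT, and averaged over the observed ramp — and reports
response-scale differences versus sham with delta-method CIs and FDR
adjustment. Requests outside the observed intensity range trigger an
extrapolation warning rather than an error.

**Johnson–Neyman.** For the linear intensity-by-pain interaction the simple
slope of intensity at pain level $m$ is $\beta_1 + \beta_3 m$ with variance
$v_{11} + m^2 v_{33} + 2 m v_{13}$. `johnsonNeyman()` evaluates the Wald
statistic on a 512-point grid over the observed pain range and refines each
significance boundary by root finding; intervals are reported only within
the observed range. The grid-plus-refinement route matches the closed-form
quadratic solution to $10^{-6}$ and generalizes to non-quadratic variance
functions.

# Repeatability

`iccTwoWay()` implements the two-way random-effects, absolute-agreement,
single-measures ICC(2,1) from ANOVA mean squares,

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n},$$

with the Satterthwaite-approximated F-based 95% CI. Absolute agreement was
chosen over consistency because between-session level shifts are
scientifically meaningful here; the consistency form ICC(C,1) is available
via `type = "consistency"`, and single measures (not averages) because the
unit of interest is one session's block measurement. Missing cells are
handled by listwise deletion, never imputation; negative estimates are
reported as computed. `iccByTargetBlock()` computes one ICC per (target,
retained block) with participants as subjects and sessions as raters,
flagging ICC ≥ 0.4 as moderate repeatability; `pairwiseSessionIcc()` does
the same for session pairs (k = 2), which exposes first-session novelty
effects as lower ICCs for pairs involving session 1.

# Heart-rate directionality

`postTrainHrChange()` compares mean heart rate in the 2 s window after each
train's end against two references: the 2 s immediately before train onset
(drift-robust, locally differenced) and a stable session baseline defined
as the mean over rest-phase samples excluding the first two blocks of the
recording. The published description of the stable baseline is ambiguous on
both the window and which "first two blocks" are excluded; this package
fixes rest-phase-only samples and recording blocks 1–2, and keeps both
deltas side by side so the choice is auditable. Negative deltas denote
deceleration. `directionSummary()` reports cell means with normal CIs per
(target, intensity) and a Spearman trend of delta against intensity per
target.

# Numerical choices and degenerate inputs

* Block windows are half-open `[onset, onset + duration)`; onsets in
  seconds from recording start. Intensities are stored as integer %MSO
  (the physical quantity); %MT labels are derived on demand, rounding to
  nearest with ties up — likewise for the final ramp intensity when
  1.2 × rMT is not an integer.
* `blockPower` requires ≥ 8 samples per window; non-finite samples
  invalidate the block (NA) rather than erroring the session. Blocks with
  fewer than two beats are invalid.
* IPFM requires rate ≥ 25 bpm; the generator floors heart rate there.
* `cleanRR` is idempotent; a gap whose expected beat count rounds to one
  is left as is rather than shifting untouched neighbors.
* ICC confidence intervals collapse to the point estimate when residual
  mean squares vanish (ICC = 1), instead of producing NaN.
* BH adjustment propagates NA/NaN p-values with a warning and preserves
  input order; ties are handled by the standard step-up on a stable sort.
* Non-converged fits are returned flagged (`converged = FALSE`), never as
  exceptions; downstream contrast and JN functions warn or refuse when the
  coefficient covariance is unusable.

# Validation strategy and problem sizes

Every estimator is tested against an independent oracle: the block-power
projection against a dense zero-padded FFT; IPFM beat counts against
fine-grid quadrature; BH against its step-up definition; ICC(2,1) against
brute-force ANOVA sums of squares over small integer matrices; the mixed
fit, evaluated at zero random-effect variance, against a hand-rolled
single-level Gamma IRLS; Johnson–Neyman boundaries against the closed-form
quadratic. End-to-end recovery is checked on replicated full-scale
simulated studies (19 × 3 × 7): the injected dose ordering must be
reproduced by the marginal contrasts in at least 95 of 100 replicates, and
the Spearman correlation between injected modulation depth and mean
estimated block power must exceed 0.9. The replicated fits use the bam
engine; single-fit checks exercise both engines. Simulation-based CI
calibration (coverage of a known multiplicative target effect, and of the
null) runs on 19-participant two-target tables drawn directly at the model
level.

# Known limitations

* The exact preprocessing and "high frequency resolution" computation of
  published HBC pipelines live in supplementary material not reproduced
  here; this package's defaults are declared substitutes, and absolute
  power values are not comparable across implementations.
* The GAM variant approximates, but does not replicate, thin-plate
  penalized smoothers; effective degrees of freedom and smooth p-values are
  engine-specific.
* The generator's pain confound is tonic by construction (see above).
* WFDB-format ECG input is not supported; use two-column CSV waveforms or
  beat-time CSVs.
* Conditional $R^2$ is correlation-based, not a Nakagawa-style variance
  partition.
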