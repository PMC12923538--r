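# CardioTMS

Heart–brain coupling (HBC) analysis for neuro-cardiac-guided transcranial
magnetic stimulation (NCG-TMS).

Repetitive TMS over the dorsolateral prefrontal cortex engages a
frontal–vagal pathway that transiently modulates heart rate. The NCG-TMS 2.0
protocol exploits this: stimulation is delivered in repeating 16 s cycles (a
5 s train of 10 Hz rTMS followed by an 11 s rest), so an effective
stimulation site entrains heart rate at the cycle frequency

```
f0 = 1 / (5 s + 11 s) = 0.0625 Hz
```

HBC is quantified per 16 s block as the spectral power of the instantaneous
heart-rate signal at exactly `f0`, via a single-frequency discrete Fourier
projection of the mean-removed segment,

```
P = (2 / N^2) | sum_n x_n exp(-i 2 pi f0 t_n) |^2   [bpm^2]
```

normalized so a pure sinusoid of amplitude `A` at `f0` gives `A^2 / 2`.
Stimulation intensity ramps across the session in 2 %MSO steps up to 120% of
the resting motor threshold, and the block-level HBC powers are analyzed with
Gamma log-link mixed-effects models (EQ-1 structure: session, target,
intensity in %MT, pain, side effects, target-by-intensity and
pain-by-intensity interactions, random intercept + session slope by
participant and random intercept by block), FDR-corrected summaries, marginal
contrasts versus sham, Johnson–Neyman intervals for the intensity-by-pain
interaction, two-way random-effects ICCs (ICC(2,1)) across sessions, and a
post-train heart-rate directionality analysis.

The package is written for researchers running or simulating such protocols:
it covers the full path from raw ECG (or beat times) to inference, and ships
a synthetic cardiac-entrainment generator (IPFM beat generation from a
parametric heart-rate model) with known ground truth for validation and
power studies.

## Worked example

```r
library(CardioTMS)

cfg <- protocolConfig()              # NCG-TMS 2.0 defaults
entrainmentFrequency(cfg)
#> [1] 0.0625

sch <- buildSchedule(cfg, rmt = 40)  # participant with rMT = 40 %MSO
sch
#> ProtocolSchedule: 26 blocks, 15 active, rMT 40 %MSO
#>   span: [ 0 , 416 ) s
subset(scheduleBlocks(sch), phase == "active")$intensity_pct_mso
#>  [1] 20 22 24 26 28 30 32 34 36 38 40 42 44 46 48

# estimator sanity: a 2 bpm sinusoid at f0 carries 2^2/2 = 2 bpm^2
t <- seq(0, 16 - 0.25, by = 0.25)
hr <- hrSignal(t, 70 + 2 * sin(2 * pi * 0.0625 * t), 4)
blockPower(hr, c(0, 16))
#> [1] 2

# simulate a small study and fit the Gamma mixed model
params <- simulationParams(nParticipants = 6, nSessions = 3, seed = 42)
sim <- simulateStudy(params)
tab <- studyHbcTable(sim)
fit <- fitGammaMixed(hbcModelFrame(tab), "glmm", engine = "bam")
mc <- marginalContrasts(fit, atMt = "average")
mc[order(mc$estimate), c("target", "estimate", "ci_low", "ci_high", "p_fdr")]
#>         target   estimate      ci_low    ci_high        p_fdr
#> 1          cm5 0.01058325 -0.01340674 0.03457323 3.872345e-01
#> 5    F3_medial 0.03565433  0.01022933 0.06107932 7.183728e-03
#> 2           F3 0.04565079  0.01952936 0.07177223 9.211609e-04
#> 3  F3_anterior 0.09938778  0.06910725 0.12966832 2.501220e-10
#> 6 F3_posterior 0.18534195  0.14565494 0.22502895 1.657984e-19
#> 4   F3_lateral 0.30228837  0.24832708 0.35624967 2.873719e-27
```

The contrasts are average differences in HBC power (bpm²) of each target
versus sham, marginalized over the intensity ramp: the recovered ordering
matches the per-target modulation gains injected by the generator (sham 0 <
5-cm 0.15 < medial 0.3 < F3 0.35 < anterior 0.55 < posterior 0.8 < lateral
1.0), with sham-like targets statistically indistinguishable from sham.

Downstream stages follow the same pattern: `iccByTargetBlock()` /
`pairwiseSessionIcc()` for repeatability, `studyHrChange()` +
`directionSummary()` for post-train heart-rate direction, `johnsonNeyman()`
for the intensity-by-pain moderation, and `runPipeline()` to execute all
stages on a study with per-recording failure isolation.

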