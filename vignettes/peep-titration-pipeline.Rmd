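---
title: "Methods: from waveforms to crossover statistics in PEEP titration experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from waveforms to crossover statistics in PEEP titration experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peepicp)
```

## The problem

Raising positive end-expiratory pressure (PEEP) in mechanically
ventilated subjects with injured lungs raises intrathoracic pressure,
which can impede cerebral venous drainage and push intracranial pressure
(ICP) up. Whether it also degrades cerebrovascular pressure reactivity —
the vasculature's ability to buffer slow arterial pressure fluctuations —
is the harder question, usually asked through the pressure reactivity
index (PRx). `peepicp` implements the complete analysis chain for
randomized crossover PEEP-titration experiments of this kind: animals
receive a stepwise PEEP ladder (5, 10, 15, 20 cmH2O, nominally 20 min per
level) in both prone and supine position, with position order randomized,
while arterial pressure (ABP), ICP, airway and esophageal pressures and
flow are recorded continuously.

Because raw animal recordings are rarely shareable, the package is built
around a synthetic physiology simulator with fully known ground truth.
Every stage of the pipeline — artifact rejection, coarse-graining,
reactivity indices, esophageal-balloon mechanics, period aggregation, and
the crossover statistics — can therefore be verified quantitatively: the
test suite asks whether programmed parameters are recovered, not merely
whether code runs.

## The simulator

`sim_config()` holds the generative model. Its components:

* **ABP** (`simulate_abp()`): baseline + vasogenic slow waves + cardiac
  pulsation (fundamental plus a small second harmonic) + ventilator-rate
  modulation + white noise. Slow waves are a band-limited Gaussian
  process confined to 0.005–0.05 Hz, the band PRx methodology targets.
  A band-limited stochastic process (rather than a deterministic
  sinusoid) is the default because it gives PRx estimates realistic
  sampling variance; `slow_wave_mode = "sinusoid"` provides a single
  tone at the geometric band center for closed-form checks. The
  stochastic mode is scaled to the RMS of a sinusoid with the configured
  amplitude so the two modes are energy-matched.
* **ICP** (`simulate_icp()`): `baseline + g*S(t) + beta*(PEEP(t) - 5) +
  pulse + noise`, where `S(t)` is the < 0.05 Hz component of the ABP
  record. The signed gain `g` is the quantity PRx should see: `g > 0`
  means slow ABP waves are transmitted passively into ICP (impaired
  reactivity, PRx > 0), `g < 0` means active counter-regulation
  (PRx < 0). `beta` is the linear PEEP→ICP coupling in mmHg per cmH2O
  above the 5 cmH2O baseline. The ICP pulse amplitude follows a one-line
  surrogate of the exponential craniospinal pressure–volume curve,
  `AMP = a0*exp(k*(meanICP - knee))` clipped below at `a0`, which gives
  the compensatory-reserve index (RAP) the rising-amplitude-with-ICP
  behaviour it exists to detect.
* **Ventilator** (`simulate_ventilator()`): volume-controlled breaths
  (constant inspiratory flow, 20% end-inspiratory pause, passive
  exponential expiration, I:E 1:2). One 5-s end-inspiratory and one 5-s
  end-expiratory zero-flow hold are embedded per PEEP period; holds are
  snapped to breath phase and last a whole number of breath cycles
  (≥ 5 s) so ventilation resumes phase-continuously on release. Plateau
  pressures obey `Pawei = PEEP + VT*(El + Ecw)` and
  `Pesei − Pesee = VT*Ecw` by construction, and a 1-Hz oscillation is
  superimposed on both pressure channels during holds with amplitude
  ratio equal to the configured Baydur ratio, so balloon validation is
  measurable.
* **Artifacts** (`inject_artifacts()`): spikes (segments forced to an
  implausible absolute level) and dropouts (segments marked invalid).
  Artifact windows are aligned to the 10-s coarse-graining grid with
  durations in whole 10-s multiples. This is a deliberate design choice:
  it makes the ground-truth bookkeeping exact (every artifact window maps
  onto whole trend windows), so the cleaning rules can be scored with no
  partial-overlap ambiguity.
* **PEEP transitions** settle exponentially with a 7.5-s time constant
  (≈ 30 s to completion), avoiding step discontinuities that would leak
  into the moving correlations.

Defaults describe an anesthetized ~25 kg pig with lavage-injured lungs:
ABP 91 mmHg, ICP 9 mmHg, heart rate 100/min, respiratory rate 35/min,
VT 0.19 L, Ecw 17 and El 65 cmH2O/L, `beta` = 0.35 mmHg/cmH2O (which
implies a 5.25 mmHg ICP rise at PEEP 20). Slow-wave amplitude (3 mmHg)
and the pressure–volume surrogate parameters are conventional
neuromonitoring values rather than measurements: quantitative intracranial
slow-wave content is not well characterized for this preparation, so
these defaults are stated once here and not tuned thereafter.
`sim_config(noise_free = TRUE)` switches off every stochastic and
oscillatory component and makes PEEP steps instantaneous; in that mode
the constructed identities hold exactly, which the test suite exploits.

What the simulator does **not** emulate: baroreflex and CO2 reactivity,
lung-injury heterogeneity, position-dependent mechanics, probe drift, or
any PbO2 sensor physics (the brain-oxygen trend is an affine function of
PaO2 plus noise). Passing recovery tests therefore demonstrates that the
pipeline is correct *given* this generative family, not that the model
captures every feature of real recordings.

## Signal processing

Cleaning follows the standard multimodal-monitoring sequence: manual
exclusion windows first (`apply_manual_exclusions()`, masking — never
deleting — samples), then automated threshold rules, then analysis on
coarse-grained data.

* **Coarse graining** (`coarse_grain()`): non-overlapping 10-s window
  means (0.1 Hz), each with its fraction of valid raw samples recorded
  as coverage. Windows under `min_coverage = 0.5` emit a missing value.
  The 50% floor is a package choice — common practice where a
  vendor-specific minimum-data criterion is not published — and is
  configurable.
* **Threshold rules** (`threshold_filter()`, `validity_rules()`): ICP
  outside [−10, 60] mmHg and CPP outside [0, 150] mmHg are rejected.
  Bounds are inclusive (a value of exactly 60 mmHg is retained): the
  rejection rules are phrased as "below"/"above", so the bounds
  themselves are treated as plausible. Rules are applied to the 10-s
  trend values by default, matching the manual-then-automated-then-trend
  processing order; nothing prevents applying them to raw waveforms
  first if a study prefers.
* **Pulse amplitude** (`pulse_amplitude()`): per 10-s window, the peak of
  the single-sided amplitude spectrum within the cardiac band. The
  spectral estimator is the default because it ignores slow drift and
  broadband noise inside the window; a time-domain half peak-to-trough
  estimator is exposed via `method = "timedomain"` for comparison.
* **PRx and RAP** (`prx()`, `rap()`, both thin bindings of
  `moving_correlation()`): Pearson correlation of the most recent 30
  paired 10-s averages (5 min), updated every minute, grid anchored at
  the record start with trailing (right-aligned) windows. A window emits
  a value only when at least `min_pairs = 15` complete pairs remain
  (half the window — again a configurable package choice); zero variance
  in a window yields a missing value rather than an error.
* **Fisher transform** (`fisher_transform()`): `artanh(r)` with values at
  ±1 clipped to ±(1 − 1e-6). Indices are analyzed on the Fisher scale
  and reported back-transformed; period summaries carry both scales
  (`PRx`, `PRx_fisher`).

## Respiratory mechanics

`detect_occlusions()` finds maximal intervals with |flow| strictly below
the threshold (default 0.02 L/s) for ≥ 3 s and classifies them
end-inspiratory vs end-expiratory by comparing the plateau against the
local airway-pressure context. `plateau_pressure()` averages the final
2 s of a hold — with 5-s holds the tail is settled, since post-occlusion
stress relaxation has a sub-second time constant. `baydur_check()`
validates balloon position on the occlusion (valid iff
0.8 ≤ ΔPes/ΔPaw ≤ 1.2, computed on the settled tail).

`derive_mechanics()` then applies the standard formulas:
`Ers = (Pawei − PEEPtot)/VT`, `Ecw = (Pesei − Pesee)/VT`,
`El = Ers − Ecw` (the additive partition holds as an identity),
`TPPei/ee = Paw − Pes` at each hold, `TPPelast = Pawei·El/Ers`,
`DP = Pawei − PEEPtot`. Three definitions deserve a note:

* **PEEPtot** is the airway pressure at the end-expiratory occlusion, not
  the set PEEP, so intrinsic PEEP is captured.
* **Peak pressures** use the synchronous convention: `Ppeakcw` is the
  esophageal maximum within the same breath as the airway maximum, so
  `Ppeakl = Ppeakrs − Ppeakcw` holds as an identity.
* **Mechanical power** uses the simplified volume-control formula
  `MP = 0.098·RR·VT·(Ppeak − (Pplat − PEEPtot)/2)` J/min; lung power
  substitutes the transpulmonary pressures, and its dependent /
  non-dependent split is a single declared fraction (default 0.5).
  These are the package's own formula choices for quantities whose exact
  computational definitions vary between laboratories; they are stated
  here precisely so results are interpretable.

A record with non-positive derived `Ers` is flagged invalid rather than
raising an error, so cohort processing continues past a bad maneuver.

## Aggregation

`summarize_periods()` produces one row per animal × position × PEEP
level: the mean of each trend/index over the period window (the
representative required for downstream analysis), with per-variable
missingness recorded. The first 2 min after each PEEP change are excluded
as settling washout by default (configurable; scaled tests use shorter
windows in proportion). `delta_from_baseline()` subtracts the
same-position PEEP-5 value, excluding baseline rows from the output.
`describe_variables()` gives normality-routed descriptive output
(mean (SD) vs median (IQR) by Shapiro–Wilk).

## Statistics

The inferential chain mirrors standard crossover practice:

* **Normality routing** (`normality_route()`): Shapiro–Wilk at 0.05;
  degenerate samples (n < 3, zero variance) take the conservative rank
  route since the test is undefined there.
* **Baseline position comparison** (`baseline_compare()`): two-sample t
  vs Mann–Whitney U by the normality screen, with Levene and Bartlett
  variance diagnostics recorded.
* **Crossover assumptions** (`crossover_assumptions()`): linear
  mixed-effects model of the baseline-differenced response with fixed
  PEEP, sequence and period terms plus the sequence-by-PEEP interaction
  (carryover), and random intercepts for animal and position-within-
  animal, fitted by REML. A wording subtlety had to be resolved here: in
  this protocol PEEP levels are applied in fixed order within each
  position block, so "period" in the within-block sense is perfectly
  confounded with PEEP level. The package therefore uses the
  crossover-theory meaning — period = first vs second position block —
  which is the only definition that yields a testable period effect.
* **Test statistics**: Satterthwaite-approximated F tests (type II) from
  `lmerTest`, not plain Wald z. With 12 animals, Wald z tests on
  between-animal terms are anticonservative by construction; the
  Satterthwaite tests hold the sequence and carryover rejection rates
  near the nominal 5% in null simulations (≈ 3% and ≈ 5%); the period
  term runs mildly high (≈ 7%), which is intrinsic to testing a
  two-level within-animal factor against only 24 position blocks —
  Kenward-Roger was evaluated and trades this for an over-conservative
  sequence test (≈ 1.5%) without fixing the period term.
* **PEEP × position ANOVA** (`peep_position_anova()`): two-way ANOVA on
  the deltas; if the interaction is non-significant positions are pooled
  and the PEEP effect re-tested by repeated-measures ANOVA with animal
  as the within-subject unit. Pooling arithmetic is configurable:
  positions averaged within animal (default, one value per animal and
  level) or kept as replicates. Assumption violations route the pooled
  test to Kruskal–Wallis (non-normal residuals) or Welch's ANOVA
  (unequal variances), and the route taken is recorded in the result.
* **Baseline covariate models** (`baseline_predictor_model()`): for each
  a-priori covariate, a mixed model of the delta on PEEP increment ×
  centered baseline covariate with the same random structure; the
  interaction slope is the quantity of interest (how the PEEP response
  changes per covariate unit). No multiplicity correction is applied —
  the covariate list is fixed in advance, and corrected screening of an
  a-priori list is a different analysis. Constant covariates are
  reported as non-identifiable rather than fitted.
* **Slope recovery** (`estimate_peep_slope()`): the mixed-model estimate
  of the PEEP→ICP coupling. On exactly degenerate (noise-free) data,
  where the mixed model's variance components vanish, the fixed-effect
  estimate falls back to ordinary least squares, which returns the same
  slope.

`simulate_summary_cohort()` generates period-summary tables directly
from the period-mean model (animal and block random intercepts +
residual noise, with optional injected sequence/period/carryover/
covariate effects). It exists because statistical calibration needs
hundreds of replicate cohorts, and the waveform stages — verified
separately — would add nothing but runtime there.

## Numerical choices and degenerate inputs

* Waveform windows use a half-sample tolerance on their boundaries, so
  floating-point jitter cannot pull a neighbouring sample into a plateau
  or hold slice.
* Correlation windows with fewer than `min_pairs` pairs, or zero
  variance, emit missing values; missingness is always propagated, never
  imputed.
* All generators draw from streams derived deterministically from the
  configured seed (one fixed offset per channel), so identical seed and
  configuration give bit-identical output while channels stay mutually
  independent.
* Verification problem sizes: reactivity sign recovery uses 50 two-hour
  records per gain condition; slope recovery uses 100 replicate cohorts
  of 12 animals with 2-min PEEP steps (the protocol scaled in time, not
  in structure); crossover calibration uses 200 null cohorts; elastance
  recovery uses a 20-point (Ecw, El) grid. These sizes were chosen so
  each property is estimated with useful precision while the whole suite
  stays convenient to run routinely.

## Limitations

The statistics are verified against the simulator's generative family;
real recordings bring non-stationarities (drug boluses, suctioning,
probe drift) that enter here only through the manual-exclusion and
threshold mechanisms. The mechanical-power and dependent/non-dependent
partition definitions are declared package conventions, not universal
standards. PbO2 is a pass-through trend with no transport physics. The
healthy-versus-injured-lung contrast that motivates such experiments is
a between-study, descriptive comparison and is deliberately out of
scope: no inferential machinery is provided for it.
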