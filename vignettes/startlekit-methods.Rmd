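---
title: "Methods: fear-potentiated startle analysis in startlekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fear-potentiated startle analysis in startlekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlekit)
```

# Scope and model

`startlekit` implements the analysis chain of a differential fear
conditioning experiment whose primary outcome is the eye-blink startle
reflex, recorded as orbicularis-oculi EMG at 1 kHz. The chain has five
stages, each usable on its own:

1. **Paradigm**: a pseudorandomized three-phase session — startle
   habituation, acquisition with partial reinforcement, immediate
   (instructed) extinction.
2. **Synthetic data**: continuous EMG sessions and whole cohorts with the
   statistical structure the analysis assumes, standing in for raw
   recordings that studies of this kind rarely deposit.
3. **Preprocessing**: 65 Hz high-pass, rectification, 40-ms moving
   average, 2 Hz drift removal.
4. **Scoring**: threshold-based response validation per probe,
   peak-amplitude extraction in a fixed target window, and
   ITI-proportional condition scores.
5. **Statistics**: 2x2 mixed ANOVA with partial eta squared, paired and
   pooled independent t-tests, Pearson correlation and chi-square, and
   contingency-awareness classification.

The scientific quantity of interest is the *differential startle
response*: the CS+ (shock-predicting cue) minus CS− (safe cue) difference
of proportional startle amplitudes, per phase. Successful acquisition
shows as a positive differential in both groups; the group contrast of the
extinction differential (the CS-type x Group interaction) is the headline
test.

# The paradigm generator

Defaults: 9 habituation tones (ITIs drawn from {12, 14, 16} s); per
conditioning phase 10 CS+ and 10 CS− of 8 s; in acquisition 5 of the 10
CS+ co-terminate with a 100-ms US; 50-ms startle probes at 4.5 or 7 s
after CS onset on 6 CS+ and 6 CS−, plus 4 ITI probes; extinction replays
acquisition's trial order, probe placement and ITI durations with no US.

Where the design is under-specified by convention, the package fixes it as
follows and treats the choices as configurable:

- *Pseudorandomization* means at most 2 consecutive trials of the same CS
  type, enforced by bounded rejection sampling (a scheduling error is
  raised if no admissible sequence exists, e.g. with a single CS type and
  more trials than the run limit).
- Reinforced and probed CS+ are drawn uniformly without replacement, so
  reinforced trials may carry probes; the probe (at or before 7 s) always
  precedes the US (at 7.9 s).
- The two probe offsets are balanced 50/50 within each CS type and phase.
- Conditioning-phase ITIs use the same {12, 14, 16} s set as habituation.
- The gap between phases defaults to 20 s. Procedurally an immediate
  extinction phase starts minutes after acquisition, but the gap carries
  no probes and no scored signal, so simulating minutes of silence would
  only add runtime; the scores are invariant to this value.

# The synthetic EMG model

Each participant is described by `participant_params()`:

- background EMG: stationary Gaussian noise, band-limited to 1–200 Hz
  (the amplifier's acquisition bandpass, applied only here, not re-applied
  in preprocessing), RMS defaulting to 2 µV;
- blink bursts: a 30–300 Hz band-limited carrier under a gamma-shaped
  envelope (shape 3, scale 7.5 ms, truncated at 120 ms; roughly 60 ms
  effective width). The envelope peak is
  `blink_gain_iti x potentiation[phase, cs] x habituation_rate^(probe ordinal - 1)`
  times a lognormal trial jitter. The burst starts `blink_latency_ms`
  (default 45 ms, jitter SD 5 ms) after probe onset, which places the
  processed peak near 65 ms — inside the 40–90 ms target window, so the
  standard windows are the correct windows for clean inputs;
- the carrier waveform is drawn once per session and reused across
  blinks. This makes the processed blink amplitude exactly proportional
  to the programmed envelope peak, so with jitters disabled the
  ITI-proportional scores recover the potentiation factors *exactly* —
  the key identifiability property the test suite asserts. Trial-to-trial
  morphology variation is represented by the amplitude and latency
  jitters instead;
- non-responses (probability 0.05 per probe) and electrode artifacts
  (probability 0.02 per trial; a 300-ms step-plus-ramp at ten times the
  blink gain).

`blink_gain_iti` (default 60 µV) and the noise RMS are free parameters:
published reports give proportional scores, not raw microvolt amplitudes,
so absolute levels are set to typical orbicularis-oculi values and all
acceptance checking of this module is property-based (scale equivariance,
parameter recovery, count conservation).

## Cohort structure

`cohort_design()` describes the population: 37 patients with major
depressive disorder (MDD) and 40 healthy controls by default. Population
potentiation means are:

| group   | acquisition CS+ / CS− | extinction CS+ / CS− |
|---------|----------------------|----------------------|
| MDD     | 1.30 / 0.85          | 0.80 / 0.80          |
| control | 1.30 / 0.85          | 1.05 / 0.70          |

i.e. identical differential potentiation during acquisition in both
groups, full extinction in patients, and a persisting CS+ > CS−
differential in controls (the immediate-extinction deficit).

Between-participant spread uses two components per phase: a shared
reactivity level (SD 0.25) and a differential deviation (SD 0.47, split
evenly between the two cells with opposite sign). These SDs were chosen
*analytically, before any test was run*, to match the standardized effect
sizes implied by the reported statistics: an acquisition CS-effect of
dz ≈ 0.45/0.47 ≈ 0.96 (the scale implied by F(1, 75) ≈ 71) and a control
extinction differential of dz ≈ 0.74 (the scale implied by a paired t
near −3.1 at n = 40). Two consequences follow rather than being tuned:
the implied probability of successful acquisition, P(differential > 0) =
Φ(0.96) ≈ 0.83, closely matches the reported 31/37 and 35/40 subset
sizes; and the power of the extinction interaction at 37 + 40 is ≈ 0.88,
which is why the headline pattern reproduces in the majority of replicate
cohorts without per-replicate adjustment.

Covariates are linked through shared standardized deviates: illness
duration (mean 10.6, SD 9.5 years, truncated positive) correlates −0.40
with the *true* extinction differential; BDI (29.2 ± 10.5) correlates
+0.41 with the true acquisition differential; age correlates 0.42 with
illness duration. Because scored differentials add measurement noise and
a participant-specific habituation scale, recovered correlations are
mildly attenuated (by a few percent) relative to these targets;
truncation attenuates them slightly further. Awareness answers make 2/37
patients unaware and everyone else fully aware.

Per-participant seeds are derived deterministically from the design seed
(a fixed 31-bit linear map), so cohorts are reproducible and stable under
cohort-size changes.

## What the generator does not emulate

Shock artifacts in the EMG, eye movements and voluntary blinks,
non-stationary background tone, electrode impedance drift, and any
dependence of blink morphology on arousal. A green test on synthetic data
establishes that the pipeline measures what the generator embeds — it
cannot establish robustness to artifact classes the generator does not
produce.

# Preprocessing

The chain applies, in order: 65 Hz high-pass, full-wave rectification,
40-ms centered moving average, 2 Hz high-pass (slow-drift removal), then
clamps residual negatives at zero so the result is a non-negative startle
response curve. Design choices:

- **Filter realisation.** No IIR filter-design library is available in
  the target environment, so both high-pass stages are zero-phase
  frequency-domain filters whose gain is the *squared* magnitude response
  of an analog 4th-order Butterworth — the steady-state equivalent of
  filtering forward and backward (filtfilt) with that Butterworth. Zero
  phase preserves the 20–110 ms latency semantics; the frequency-domain
  realisation avoids the numerical fragility of a direct-form IIR at a
  2 Hz cutoff on 1 kHz data. Edges are handled by reflection padding
  (2 cycles of the cutoff frequency). One visible consequence: the 2 Hz
  stage leaks a slow positive sidelobe of a few percent of a burst's peak
  into the neighbouring ±0.3 s; it is far below any detection threshold
  with realistic baselines.
- **Moving average**: 40 samples at 1 kHz, centered (even windows extend
  one sample further into the past), edges by reflection, so trial
  onsets are not biased.
- **Order of drift removal**: the documented chain removes drifts after
  smoothing; `drift_after_smoothing = FALSE` moves the 2 Hz stage before
  rectification for sensitivity analyses, since the conventional
  description is ambiguous on this point.
- Degenerate inputs: constant recordings pass through as all-zero output
  (not an error); non-1000 Hz rates are rejected (resampling is out of
  scope).

## Artifact marking

Visual artifact rejection is replaced by an automated surrogate. The
discriminating signature of an electrode step/drift is its *slow*
content: blink bursts are zero-mean 30–300 Hz events that vanish in a
100-ms moving average of the raw signal (observed slow residue ≤ 10 µV
even for 250 µV blinks), while steps survive it at nearly full amplitude
(≥ 200 µV for the default artifact model). The default rule therefore
masks samples whose slow component exceeds 50 µV (with a raw-amplitude
ceiling at 1000 µV and an optional slope rule), dilated by 50 ms. Trials
whose baseline or response windows overlap the mask are invalidated with
reason `artifact`. Rules set to `Inf` are disabled.

# Response definition and scoring

For each probe: the threshold is `baseline_mean + 3 x baseline_sd`
computed over the 500 ms of processed signal before probe onset. A
response is valid if the curve first strictly exceeds the threshold
within 20–110 ms after probe onset and falls back below it by the end of
that window ("fell back below" is bound to the same window, since the
definition binds both events to one latency window). The amplitude is
the maximum of the processed signal in the fixed 40–90 ms target window
minus the baseline mean, floored at zero — which makes a zero signal
score 0 and matches the proportional-score semantics. Invalid trials
carry reason codes (`no_crossing`, `late_onset`, `no_return`,
`artifact`).

Numerical edge cases, decided here:

- *Degenerate baseline* (SD = 0, e.g. noise-free synthetic data): the
  trial is valid only if the curve strictly exceeds the baseline mean,
  and the return-below condition is waived — a zero-width threshold band
  makes "returning below" meaningless, as the processed blink tail stays
  infinitesimally positive beyond the window.
- "3 SDs of baseline" is read as mean + 3 SD (the standard EMG onset
  convention), with the multiplier configurable.

Cell means use valid trials only (never zero-filled). The reference value
is the mean *acquisition* ITI startle amplitude — ITI startle habituates
across the session, so phase-specific referencing would occlude
acquisition-to-extinction changes, while acquisition ITIs show minimal
habituation; both CS conditions in both phases are divided by this one
reference. Participants with no valid acquisition ITI probe are flagged
unscorable and excluded explicitly, never silently zeroed. Habituation
probes contribute to no score cell. The successful-acquisition filter
retains strictly positive acquisition differentials.

The trial-exclusion rule (invalid trials dropped from the six-trial
averages, no minimum-valid-trial criterion beyond one valid trial per
cell) is a package decision; conventional descriptions do not state how
non-responses enter the averages.

# Statistics

The 2x2 mixed ANOVA (Group between, CS-type within) is computed from
closed-form contrasts: for a two-level within factor, the between part is
a one-way ANOVA on subject means and the within part is carried by the
per-subject CS+ − CS− difference. Unbalanced groups use unweighted
(Type III) marginal means, reproducing the output of the major
statistical packages; with balanced groups this coincides with the
classical Type I decomposition, which the tests verify against
`stats::aov`. Partial eta squared is SS_effect / (SS_effect + SS_error),
and the identity η²p = F/(F + df_den) holds exactly. Participants missing
a cell are dropped listwise with a logged count. For a single group the
function degrades to the one-way repeated-measures ANOVA, whose F equals
the squared paired t.

Independent t-tests default to the pooled-variance (Student) form, with
Welch available via `var_equal = FALSE`; summary-statistic entry points
(`independent_t_summary()`) recompute printed demographic tables without
raw data. Pearson correlations report r, df = n − 2 and two-tailed p;
the chi-square is Pearson's without continuity correction. No
multiple-testing correction is applied anywhere; all p-values are
two-tailed at α = .05. Awareness classification maps the two
CS-identification answers to fully aware / partially aware / unaware.

# Monte-Carlo validation strategy

Two generators feed the validation suites at different costs:

- the **full-EMG path** (schedule → recording → preprocessing → scoring)
  validates the signal chain: exact parameter recovery on noise-free
  sessions, unbiased recovery within Monte-Carlo error on noisy sessions,
  scale equivariance, artifact handling, and the headline group pattern
  on a small number of full replicate cohorts at study scale;
- the **score-level path** (`simulate_cohort_scores()`) draws
  proportional scores directly from the same participant-level truth with
  the trial-sampling noise implied by 6 CS and 4 ITI probes. It feeds the
  calibrations that need hundreds of replicates — the type-I error of the
  interaction test under a null design (rejection rate 0.05 ± 0.02 at 500
  replicates) and correlation-recovery checks — where full EMG simulation
  would cost hours for no additional information about the statistics
  layer.

# Known limitations

- The EMG container is single-channel; EDF input is not supported (no
  EDF codec exists in the supported dependency set) — continuous signals
  interchange as headered TSV.
- The artifact surrogate targets step/drift transients only; it is not a
  general artifact classifier and deliberately errs on the permissive
  side for blink-like events.
- The score-level generator assumes Gaussian trial-sampling noise on the
  proportional scale; it is a calibration device for the statistics
  layer, not a substitute for the EMG path.
- Proportional scores inherit a small positive bias of order CV² of the
  ITI reference mean (a ratio-of-means estimator with a 4-probe
  denominator); at default settings this is below 2% and within the
  Monte-Carlo bands the tests assert.

# Worked example

```{r example, eval = FALSE}
library(startlekit)

res <- run_pipeline(pipeline_config(
  design = cohort_design(n_mdd = 37, n_control = 40),
  seed = 11
))
res$stats$anova$extinction
autoplot(res)
plot_extinction_correlation(res$scores)
```

At seed 11 this prints an extinction-phase interaction of
F(1, 74) = 17.20, p < .001, η²p = 0.189 (one participant listwise-dropped
for an unmeasurable extinction cell), with the control paired test
significant (t(39) = −4.80) and the patient paired test not
(t(35) = 0.83) — the qualitative pattern the generator encodes. Exact
values vary with the seed.
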