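# startlekit

Analysis toolkit for **fear-potentiated startle** experiments: differential
fear conditioning indexed by the eye-blink startle reflex, recorded as
orbicularis-oculi EMG at 1 kHz.

In these experiments a participant learns that one visual cue (CS+) predicts
an aversive shock (US) while another (CS−) is safe; brief loud noise probes
elicit a reflexive eye blink whose amplitude is potentiated in the presence
of the feared cue. The package implements the full chain from paradigm to
group statistics:

- **Paradigm generation** — pseudorandomized three-phase sessions
  (habituation, acquisition with 50% partial reinforcement, immediate
  instructed extinction), with exact probe/reinforcement bookkeeping and a
  BIDS-events-style TSV interchange format.
- **Synthetic EMG cohorts** — continuous 1 kHz sessions with blink bursts
  time-locked to probes, background EMG noise, group-specific
  CS-type × phase potentiation structure, session-wide startle habituation,
  non-responses, electrode artifacts, and clinical covariates linked to the
  true conditioning strength.
- **Preprocessing** — the standard offline chain: 65 Hz high-pass,
  full-wave rectification, 40-ms moving average, 2 Hz drift removal
  (zero-phase throughout), plus automated step/drift artifact masking.
- **Response scoring** — per-probe validation (threshold =
  baseline mean + 3 SD of a 500-ms baseline; onset and return within
  20–110 ms), peak amplitude in the fixed 40–90 ms target window, and
  **ITI-proportional scores**: each CS condition mean divided by the mean
  acquisition intertrial-interval startle amplitude, with the differential
  (CS+ − CS−) as the strength-of-conditioning measure.
- **Statistics** — 2×2 mixed Group × CS-type ANOVA with partial eta
  squared (η²p = SS_eff / (SS_eff + SS_err)), paired and pooled/Welch
  independent *t*-tests (raw or summary-statistic input), Pearson
  correlation, Pearson chi-square, and contingency-awareness
  classification.

Everything is tibble-first and pipe-friendly; fitted ANOVA objects have
`tidy()`/`glance()` methods and results have `autoplot()`.

## Worked example

```r
library(startlekit)

res <- run_pipeline(pipeline_config(
  design = cohort_design(n_mdd = 37, n_control = 40),
  seed = 11
))
res
```

```
<startle_results> 77 participants (0 unscorable)

-- acquisition --
2x2 mixed ANOVA (acquisition phase): N = 77, dropped = 0
        effect                                           label
         group     F(1, 75) = 0.02, p = 0.881, eta_p^2 = 0.000
       cs_type F(1, 75) = 45.99, p = 2.38e-09, eta_p^2 = 0.380
 cs_type:group     F(1, 75) = 0.58, p = 0.449, eta_p^2 = 0.008

-- extinction --
2x2 mixed ANOVA (extinction phase): N = 76, dropped = 1
        effect                                           label
         group   F(1, 74) = 8.95, p = 0.00376, eta_p^2 = 0.108
       cs_type   F(1, 74) = 9.55, p = 0.00282, eta_p^2 = 0.114
 cs_type:group F(1, 74) = 17.20, p = 8.87e-05, eta_p^2 = 0.189
...
```

Reading the output: in **acquisition** both groups acquire differential
fear (large CS-type main effect, no Group or interaction effect — the
groups condition equally). In **extinction** the significant
CS-type × Group interaction shows the groups extinguish differently: the
patient group's CS+/CS− difference has vanished (paired t(35) = 0.83,
n.s.) while controls keep responding differentially (t(39) = −4.80,
p < .001). One participant was listwise-dropped for an unmeasurable
extinction cell. `res$scores` holds the per-participant proportional
scores, `res$trials` the per-probe detections, and
`autoplot(res)` / `plot_extinction_correlation(res$scores)` draw the
standard figures.

Individual stages compose the same way:

```r
sched  <- build_schedule(schedule_config(seed = 1))
rec    <- simulate_emg_session(sched, participant_params(), seed = 1)
sig    <- mark_artifacts(preprocess_emg(rec))
resp   <- detect_responses(sig)
scores <- score_participant(resp)
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete synthetic pipeline at study scale (37 patients + 40
controls, default paradigm) from the given seed — schedule generation, EMG
simulation, preprocessing, scoring and the full statistics layer — prints
the resulting group-level report, and writes the JSON acceptance output to
`--out`.

## Package layout

| file | contents |
|------|----------|
| `R/schedule.R` | paradigm configuration and schedule builder |
| `R/simulate.R` | participant/cohort models and EMG synthesis |
| `R/preprocess.R` | EMG containers, processing chain, artifact masking |
| `R/scoring.R` | response detection, validation and proportional scoring |
| `R/stats.R` | ANOVA, t-tests, correlation, chi-square, awareness |
| `R/pipeline.R` | end-to-end runner, cohort statistics, manifest |
| `R/plots.R` | ggplot2 figures |
| `vignettes/startlekit-methods.Rmd` | the model, its assumptions and design decisions |
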