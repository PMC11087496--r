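# floorgait

Functional gait assessment from ambient floor vibration, for researchers
and engineers working on contactless gait monitoring in muscular
dystrophy (MD) and related movement disorders.

When a person walks, every footstep applies a short force to the floor and
excites a vibration impulse that cheap geophones on the floor surface can
record. `floorgait` turns such multi-sensor voltage recordings into gait
health information:

* **Impulse detection** — a sliding-window threshold detector (mean
  absolute amplitude above `noise mean + 3 × noise SD`, estimated from a
  pure-noise reference) followed by footstep plausibility filtering:
  transients must last 0.2–0.6 s and occur in runs of ≥ 3 consecutive
  impulses, which rejects door slams, dropped objects and other isolated
  disturbances. Zero-phase lowpass and spectral-subtraction Wiener
  filtering denoise the accepted signal.
* **Symptom-based features** — foot-strike times from a Morse-wavelet
  envelope of the 5–25 Hz floor-resonance band, giving step time
  (t<sup>i+1</sup> − t<sup>i</sup>), cadence ((N−1)/(t<sup>N</sup> −
  t<sup>1</sup>)), and step-time variability; a left–right symmetry score
  `1 − mean |X90ᵢ₊₁ − X90ᵢ| / (0.5 (X90ᵢ₊₁ + X90ᵢ))` over per-footstep
  90th-percentile amplitudes; and the probability of toe initial contact
  from a quadratic-kernel SVM over normalized footstep spectra.
* **Signal-based features** — impulse moments, dominant strike/off
  frequencies, PSD band powers, per-trace energy variability and the
  spectrum of the most representative (highest-energy unclipped) footstep.
* **A normative functional scale** — the 100-m run time relative to the
  healthy reference speed `36.72 − 1.51·age + 0.26·weight/height²`,
  discretized into MD progression stages 0–7.
* **A hierarchical stage predictor** — step-level features feed a
  12–256–64 network, trace-level features a 20–128–32 network, and
  person-level features (aggregated probabilities + age, gender, BMI) a
  9–64 network; each level is pretrained against stage labels (teacher
  enforcing) and the stack is then fine-tuned end to end, predicting
  stages 0–5 per person.
* **A synthetic gait-vibration simulator** — annotated footstep-impulse
  traces and labeled cohorts with stage-dependent cadence, toe-contact and
  symmetry trends, sensor-distance attenuation, noise and distractor
  transients, so the entire pipeline is testable without any recordings.

## Worked example

```r
library(floorgait)

# functional scale: a 10-year-old, 30 kg, 1.40 m, running 100 m in 60 s
b <- biometrics(age = 10, weight = 30, height = 1.4)
functional_stage(b, actual_100m_time = 60)
#> $percent
#> [1] 42.66599
#> $stage
#> [1] 4

# simulate one stage-3 walking pass over a 4-sensor walkway
profile <- gait_profile_for_stage(3, seed = 2)
trace <- generate_walk_trace(profile, n_steps = 10, noise_sd = 0.02,
                             seed = 42)
trace
#> <fg_trace> 10 footsteps, 4 sensors, 12.93 s @ 500 Hz

# detect footsteps on one sensor and extract symptoms
rec <- trace$recordings[[2]]
noise <- estimate_noise_stats(rec)
accepted <- filter_footstep_impulses(detect_impulses(rec, noise))
nrow(accepted)
#> [1] 10
strikes <- detect_foot_strikes(wavelet_band_envelope(rec))
cadence(strikes)
#> [1] 116.0317
impulses <- segment_footsteps(rec, accepted)
symmetry_score(sapply(impulses, x90_amplitude))
#> [1] 0.6688719
```

All ten simulated footsteps are recovered; the estimated cadence (116
steps/min) sits within a few steps/min of the generator's 119, and the
symmetry score ≈ 0.67 reflects the stage-3 left–right force ratio of 0.68
(alternating amplitudes a, ra give a score of 1 − 2(1−r)/(1+r) ≈ 0.62 in
expectation, before amplitude jitter).

The full synthetic recovery experiment — cohort generation, detection,
features, rebalancing, hierarchical training, evaluation — runs in one
call:

```r
res <- run_recovery_experiment(seed = 1)
unlist(res$accuracy)
#>      step     trace    person
#> 0.7384615 0.9833333 1.0000000
```

Accuracy improves from the step level through trace aggregation to the
person level, which is the point of the hierarchical design.

## Command-line interface

A thin CLI over the same functions lives at `inst/cli/floorgait.R`
(installed under `system.file("cli", package = "floorgait")`):

```sh
Rscript inst/cli/floorgait.R simulate --subjects 12 --seed 7 --out cohort/
Rscript inst/cli/floorgait.R detect --recordings cohort/s01/trace01_recordings.csv --out events.csv
Rscript inst/cli/floorgait.R scale --biometrics subjects.csv --out stages.csv
Rscript inst/cli/floorgait.R recover --seed 7 --out report.json
```

Commands: `simulate`, `detect`, `features`, `scale`, `train`, `predict`,
`evaluate`, `recover`. All accept `--seed`, `--out` and a YAML `--config`
(schema in `default_pipeline_config()`); seeded runs are byte-identical.

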