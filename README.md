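# erpdistract

Simulation and analysis of event-related potentials (ERPs) from an
auditory-visual distraction paradigm, for researchers who need a fully
verifiable ERP measurement chain: every stage is validated by parameter
recovery from synthetic EEG with known ground truth.

## The paradigm and the measures

Participants ignore a tone stream (70% standard, 15% deviant, 15% novel
sounds) while responding to visual Go stimuli that follow each sound at a
300-ms SOA (500 A-V pairs, 2 blocks). Rare sounds capture attention: Go
reaction times rise after novel sounds, and the difference waveforms
(Novel − Standard, Deviant − Standard) carry four components, measured as
window-constrained peaks:

| component | polarity | window (ms) | amplitude at | latency at |
|-----------|----------|-------------|--------------|------------|
| MMN       | −        | 100–250     | Cz           | Cz         |
| e-P3a     | +        | 280–400     | Fz, Cz, Pz   | Cz         |
| l-P3a     | +        | 350–500     | Fz, Cz, Pz   | Cz         |
| RON       | −        | 400–700     | Fz, Cz       | Cz         |

Amplitude is the signed peak value relative to the zero baseline
(µV); latency is the time from sound onset to the peak (ms). Because the
two P3a windows overlap, the l-P3a search runs strictly later than the
e-P3a peak found at Cz (the phases are consecutive). Group comparisons
(Young / Middle-aged / Old; N = 18/20/15) use mixed-design ANOVAs — e.g.
Group × Difference × Electrode — with Greenhouse-Geisser correction
(ε from the contrast-score covariance), partial η² = SS_eff/(SS_eff+SS_err),
Bonferroni post-hocs, and Cohen's d = |m₁−m₂| / √((s₁²+s₂²)/2) between
groups.

The package contains: a synthetic-data generator whose defaults are the
published group parameter table (task timeline, RT model, multichannel EEG
with embedded components, 1/f background, alpha, blinks); the signal chain
(EOG regression, epoching, zero-phase 0.1–30 Hz Butterworth filtering,
baseline correction, ±100 µV + first-five-per-block rejection, averaging,
difference waves); peak measurement; voltage and spherical-spline CSD
topographies; and the statistics engine.

## Worked example

Render the clean Young-group Novel−Standard difference wave from the
default parameter table and measure it:

```r
library(erpdistract)
dw <- render_difference_wave("Young", "NS")
measure_components(dw)
#>   component electrode amplitude latency identifiable
#> 1       MMN        Cz      -2.8     163         TRUE
#> 2      eP3a        Fz      14.8     297         TRUE
#> 3      eP3a        Cz      19.3     297         TRUE
#> 4      eP3a        Pz      13.2     297         TRUE
#> 5      lP3a        Fz      11.2     370         TRUE
#> 6      lP3a        Cz      12.7     370         TRUE
#> 7      lP3a        Pz      11.0     370         TRUE
#> 8       RON        Fz      -3.5     527         TRUE
#> 9       RON        Cz      -2.7     527         TRUE
```

The measured values reproduce the embedded parameters exactly — a 2.8-µV
MMN at 163 ms, a 19.3-µV e-P3a at Cz, a −3.5-µV RON at Fz — which is the
generator's calibration property: compact-support kernels guarantee that
peak measurement inverts rendering.

Behavioral analysis of a stochastic 53-subject cohort:

```r
tr <- simulate_cohort_rts(master_seed = 1)
ra <- rt_analysis(tr)
ra$anova[, c("effect", "df1", "df2", "F", "epsilon", "p", "eta_p2")]
#>            effect df1 df2     F epsilon        p eta_p2
#> 1           group   2  50 25.54      NA 2.28e-08 0.5054
#> 2       condition   2 100 83.29   0.972 1.79e-21 0.6249
#> 3 group:condition   4 100  1.62   0.972 1.76e-01 0.0609
```

Both aging (Group) and distraction (Condition: Novel slower than Standard
and Deviant) effects are recovered, with GG-corrected p-values and effect
sizes; `ra$posthoc_group` shows the Young group responding ~140–170 ms
faster than both older groups (d ≈ 2.1–2.2).

A full run — simulate, preprocess, measure, map, test, write CSVs and a
manifest — is one call:

```r
run_pipeline(run_config(seed = 7, out_dir = "erp_run"))
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --seed 7 --out erp_run`.

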