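# fieldlab

Analysis and simulation of extracellular field-potential recordings from
hippocampal slices, aimed at electrophysiologists quantifying synaptic
strength and plasticity at the CA3–CA1 (Schaffer collateral) synapse and at
anyone who needs a fully seeded, testable stand-in for such recordings.

The package implements the standard slice-electrophysiology measurements:

* **Input–output curves** — fEPSP initial slope and fiber-volley amplitude
  vs stimulus current (0–320 µA in 10 µA steps, six sweeps averaged per
  intensity).
* **fEPSP initial slope** — least-squares fit over the 20–80 % rising
  phase, robust to population spikes on the falling phase.
* **Paired-pulse ratio** — `PPR = slope₂ / slope₁` at a 50 ms interval,
  with mono-exponential subtraction of the first response's tail.
* **Theta-burst LTP** — one bout of weak TBS (5 pulses at 100 Hz × 10
  bursts at 200 ms); magnitude as % of the 20-min baseline slope over a
  44–59 min post-tetanus window; experiments with more than 8 % baseline
  variance (CV of 1-min binned slopes) are excluded.
* **Tetanus depolarization** — rectified area under the curve over 100 ms
  from each burst onset, averaged across the ten bursts (mV·ms).
* **Modified Coastline Burst Index** — `mCBI = Σ |V_{x+1} − V_x|` over a
  post-stimulus window (default 25–125 ms at 10 kHz), a measure of
  repetitive population-spike activity.
* **Group statistics** — Welch's unequal-variance two-tailed *t*-test
  (raw samples or published n/mean/SE summaries), single-pass two-sided
  Grubbs outlier screening, mean ± SE summaries, and noncentral-*t* power.

Because raw recordings for this preparation are not publicly deposited, a
seeded generative simulator is part of the package: fiber volleys follow a
Hill recruitment curve of stimulus current, fEPSPs are dual exponentials
scaled by recruitment × facilitation × potentiation, population spikes ride
the fEPSP decay, and Gaussian noise plus slow drift complete the sweep.
Condition presets (`"air"`, `"hyperoxia"`) reproduce the direction of the
published group effects; see the methods vignette
(`vignettes/field-potential-analysis.Rmd`) for the model and every
numerical convention.

## Worked example

```r
library(fieldlab)

# one simulated control slice, noise-free, and its input-output curve
p  <- preset("air", noise_sd = 0)
io <- analyze_io(simulate_experiment(p, build_io_ramp()))
max(io$curve$mean_slope)      # 0.1798052  mV/ms at 320 uA
fv_amplitude(p, 320)          # 0.2771441  mV   (generator closed form)
io$curve$mean_fv[33]          # 0.2769171  mV   (recovered from the sweeps)

# paired-pulse ratio recovers the generator's facilitation factor
ppr <- analyze_ppr(simulate_experiment(preset("air", noise_sd = 0, seed = 5),
                                       build_paired_pulse(160, n_sweeps = 2)))
ppr$ppr                       # 1.500042   (f50 = 1.5)

# a full 6 + 6 cohort with all analyses and group comparisons
co <- run_cohort(n_per_group = 6, seed = 7)
print(co)
#> <fieldlab_cohort> air vs hyperoxia, n = 6/6, seed = 7
#>   io_max_slope     0.1811 vs   0.5219   p = 6.59e-05
#>   io_max_fv        0.2879 vs   0.5167   p = 2.62e-05
#>   ppr               1.503 vs    1.472   p = 0.336
#>   ltp               134.7 vs    215.4   p = 1.48e-15
#>   auc               97.21 vs    261.3   p = 0.000361
#>   mcbi                  1 vs    1.104   p = 0.00063
#>   baseline_fv      0.1643 vs   0.2432   p = 1.72e-05
report(co, "results/cohort_seed7")   # CSV tables + PNG figures + manifest
```

Reading the cohort printout: the hyperoxia group shows larger maximal I/O
slope and fiber volley, more LTP (215 % vs 135 % of baseline), a larger
tetanus depolarization and a higher relative mCBI, while the paired-pulse
ratio does not differ (p = 0.34) — facilitation, hence release
probability, is unchanged. This is the qualitative pattern the analyses
are designed to resolve.

A thin command-line wrapper over the same functions ships in
`inst/cli/fieldlab.R` (`simulate`, `metrics`, `analyze`, `stats`,
`cohort`, `report` subcommands).

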