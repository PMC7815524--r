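---
title: "Analysing hippocampal field potentials with fieldlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing hippocampal field potentials with fieldlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldlab)
```

## The measurement problem

Extracellular recordings at the CA3–CA1 (Schaffer collateral) synapse probe
basal synaptic strength and plasticity through a small set of standard
quantities: input–output (I/O) curves of the field EPSP (fEPSP) initial
slope and of the fiber-volley amplitude against stimulus current; the
paired-pulse ratio (PPR) at a 50 ms interval; the magnitude of long-term
potentiation (LTP) induced by theta-burst stimulation (TBS), expressed as a
percentage of the pre-tetanus baseline slope; the postsynaptic
depolarization during the tetanus, measured as the area under the curve
(AUC) over 100 ms from each burst onset; and a modified Coastline Burst
Index (mCBI) that quantifies repetitive population-spike activity.
`fieldlab` implements all of these measurements, the group statistics used
to compare an exposed and a control cohort (Welch's unequal-variance
*t*-test with Grubbs outlier screening and a power calculation), and a
seeded generative simulator so that every stage of the pipeline can be
validated without laboratory recordings.

## The generative model

No deposited raw data exist for this preparation, so the simulator is a
first-class, tested component: it defines the study conditions under which
the analyses are exercised. Each sweep is a closed-form sum evaluated on a
10 kHz sample grid (0.1 ms per sample, 200 ms per sweep, stimulus at
20 ms), in mV and ms:

* **Stimulus artifact** — a fast transient `artifact_amp * exp(-t/0.1 ms)`
  at each pulse (5 mV default).
* **Fiber volley** — a negative alpha function `-A(I) * s*exp(1-s)` with
  `s = (t - latency)/tau`, latency 0.7 ms and tau 0.3 ms, peaking 1.0 ms
  after the pulse. Its amplitude follows Hill recruitment
  `A(I) = fv_max * I^h / (I^h + i_half^h)` (`i_half` 80 uA, `h` 1.8),
  saturating over the 0–320 uA ramp the way recruitment curves do in
  slices.
* **fEPSP** — a normalized dual exponential (rise 2 ms, decay 20 ms)
  starting 4 ms after the pulse, with peak
  `syn_gain * A(I) * F_k * P(t)`. The 4 ms onset latency leaves the
  fiber volley fully separated from the fEPSP rise, which is what makes
  noise-free parameter recovery exact; with the control gain of 2 the
  baseline fEPSP is ~0.5 mV at half-maximal stimulation, the amplitude the
  protocol targets.
* **Facilitation** — pulse *k* is scaled by
  `F_k = 1 + (f50 - 1) * exp(-(dt - 50)/tau_f)` where `dt` is the interval
  to the previous pulse, so the paired-pulse ratio at 50 ms is `f50`
  exactly and facilitation decays with `tau_f = 250` ms. The same kernel
  acts within theta bursts.
* **Potentiation** — from tetanus onset,
  `P(t) = 1 + (p_ss - 1)(1 - e^{-t/tau_ltp}) + a_ptp e^{-t/tau_ptp}`
  (min), an LTP expression time constant of 5 min plus a post-tetanic
  transient (amplitude 0.8, decay 2 min).
* **Population spikes** — Poisson-distributed brief negative alpha spikes
  (0.3 mV, 0.3 ms) riding the fEPSP falling phase. The expected count
  scales with relative recruitment `A(I)/fv_max`, so spikes appear on
  sizeable responses rather than at threshold, as in real dendritic
  recordings of hyperexcitable tissue.
* **Noise and drift** — i.i.d. Gaussian noise (0.02 mV default) and a slow
  additive offset (`drift_rate` mV per minute of experiment time).

Responses to successive pulses sum linearly. A theta-burst episode is
represented as ten 200 ms burst sweeps (five pulses at 100 Hz each, bursts
200 ms apart); facilitation carry-over across the 200 ms gap is below
`(f50-1) * e^{-150/tau_f}` ≈ 0.03 and is neglected.

### Condition presets

`preset("air")` and `preset("hyperoxia")` encode the two exposure groups.
They differ **only** in maximal recruitment (`fv_max` 0.30 vs 0.55 mV),
synaptic gain (2.0 vs 3.0), steady-state potentiation (`p_ss` 1.34 vs
2.17), and population-spike rate (0 vs 1.5 per response); `f50` is
identical, since paired-pulse facilitation does not differ between groups.
These presets reproduce the *direction* of the group effects — stronger
I/O curves, larger fiber volleys, more LTP, larger tetanus depolarization,
higher mCBI, unchanged PPR — not any particular animal's numbers, which are
not derivable from published group summaries. The `p_ss` values are chosen
so noise-free LTP magnitudes land at 134 % and 217 % of baseline, the
calibration grid the recovery tests use. Cohorts add between-slice
biological variability as a lognormal factor (10 % CV) on recruitment and
gain, drawn from each slice's seed.

### Reproducibility

All randomness flows from one integer seed. A recording seeds a 31-bit
multiplicative mix, every sweep draws from a deterministically derived
sub-stream (`withr::with_seed`), and cohort slices derive their seeds from
`(seed, condition index, slice index)`, so identical seeds give
bit-identical recordings independent of evaluation order.

## Measurement definitions and numerical choices

* **Baseline voltage** is the mean over `[0, onset - 2 ms]`. All
  amplitudes, slopes and areas are deviations from it, which makes every
  measure invariant to constant offsets (and hence to the simulator's
  drift term).
* **Stimulus onset** is the annotated pulse time when present, otherwise
  the first sample deviating from the pre-window mean by more than
  `stim_z` (default 6) pre-window standard deviations, with a 1 uV floor
  for noise-free traces.
* **Fiber volley** — magnitude of the most negative deviation in
  `onset + [0.5, 2.5]` ms, before the configured fEPSP window.
* **Initial slope** — least-squares line through the samples whose
  deviation lies between 20 % and 80 % of the fEPSP peak on the rising
  phase (the field-standard window; the source protocol does not define
  one). The peak is the *first* prominent, broad local maximum of the
  deviation in `onset + [2.5, 30]` ms: prominence is assessed over
  ±0.5 ms, and "broad" requires the deviation half a millisecond away to
  retain at least half the height, which prevents narrow population spikes
  on the falling phase from capturing the fit. When noise exceeds 5 % of
  the peak, the fit region is located on a 5-sample moving average
  (fitting still uses raw samples), and a peak below four pre-stimulus
  standard deviations is treated as "no identifiable fEPSP" (slope 0)
  rather than an error — important for the zero- and near-threshold
  intensities of an I/O ramp. Fewer than three usable rise samples raises
  a resolution error.
* **AUC** — trapezoidal integral of `max(0, baseline - V)` (rectified
  depolarizing negativity) over `[onset, onset + 100 ms]`, reported in
  mV·ms as a positive depolarization magnitude.
* **mCBI** — `sum(|V[x+1] - V[x]|)` over the window `[25, 125]` ms, the
  summation limits of the index definition; the surrounding text of the
  source also mentions 25–70 ms, so the window is configurable
  (`analysis_config(windows = list(mcbi_window = c(25, 70)))`). The sample
  count actually used is recorded on the result rather than reconciled
  with any nominal count. Group values are reported relative to the
  control-group mean.
* **PPR** — the first response's decaying tail is fitted with a
  mono-exponential on `[onset1 + 12 ms, onset2 - 1 ms]` and subtracted
  before the second slope is measured; at a 50 ms interval the first fEPSP
  tail is ~10 % of its peak and would otherwise bias the ratio. The
  headline PPR is `mean(slope2)/mean(slope1)` across sweeps — the ratio of
  means, which is unbiased under measurement noise, whereas the mean of
  per-sweep ratios inherits a Jensen bias of order the squared
  coefficient of variation of slope 1. Per-sweep ratios are retained.
* **Baseline stability** — the inclusion statistic is the coefficient of
  variation (percent) of 1-min binned mean slopes about the overall
  baseline mean; experiments above 8 % are excluded. The source states the
  8 % limit but no formula; binned CV is the choice here, and exclusion is
  monotone in baseline wobble by construction. Exclusion applies to the
  LTP-derived metrics (LTP, tetanus AUC, mCBI), which come from the same
  recording.
* **LTP magnitude** — slopes normalized to the 20-min baseline mean
  (baseline ≡ 100 % exactly), time binned per minute around tetanus onset,
  magnitude averaged over the analysis window. The protocol text calls
  this window "the last 5 min" yet prints 44–59 min; the printed 15-min
  interval is used as the default because it is the more precise
  statement, and it is configurable.
* **~50 % of maximal response** — operationalized as the ramp intensity
  whose mean slope is nearest half the I/O maximum; this intensity then
  drives the paired-pulse and LTP protocols of that slice.
* **Tetanus AUC** — per-burst AUC over `[burst onset, onset + 100 ms]`,
  averaged over the ten bursts. Whether the original measurement was per
  burst or per episode is not stated; the per-burst mean is this package's
  convention.

## Statistics

"Student's *t*-test assuming unequal variance" is implemented as Welch's
test (the unequal-variance clause is operative): `t = (m_a - m_b) /
sqrt(se_a^2 + se_b^2)` with Welch–Satterthwaite fractional degrees of
freedom, two-tailed. It accepts published summaries (n, mean, SE) as well
as raw samples, which is how the package can reproduce a *p*-value from
printed group statistics. Grubbs screening is two-sided and single-pass
(at most one removal per group per metric). Power uses the noncentral *t*
distribution and includes both rejection tails; `power.t.test`, which
neglects the opposite tail, agrees to within ~0.005 and serves as the
cross-check. Both-group zero variance with equal means returns *p* = 1 by
convention; with unequal means it is a degenerate-input error.

## What the tests do and do not show

The acceptance suite verifies: exact equivalence of the mCBI to a
brute-force loop (and its offset/scaling invariances); noise-free recovery
of `f50`, `p_ss` (against the closed-form window average of `P(t)`) and
the Hill recruitment curve to 1–2 %; recovery within 5 % under 0.05 mV
noise at recording-scale sweep counts (6 sweeps per intensity, 120
baseline sweeps, 20 seeds); Welch/Grubbs/power agreement with independent
references and an empirical type-I error within [0.03, 0.07]; exact
protocol arithmetic (50 TBS pulses, 120 baseline sweeps, 33 × 6 ramp
sweeps); direction of all five group effects in 20 seeded cohorts of
6 + 6 slices with a non-significant PPR in at least 18; and the 4 % vs
10 % behaviour of the inclusion rule. Problem sizes (20 cohorts, 20 seeds,
full-length sweeps) are chosen so the whole suite runs on a laptop-class
single core in minutes.

Passing these tests shows the *pipeline* is correct under the generative
model's assumptions. Real slice recordings violate several of them —
synaptic responses are not exactly linear in recruitment, noise is not
white, population spikes are not Poisson, drift is not purely additive,
and electrode artifacts are richer than a single exponential — so
agreement with the simulator does not certify accuracy on any particular
rig's data. The measurement conventions (20–80 % slope window,
tail-subtracted PPR, binned-CV inclusion) are nonetheless the ones a
practitioner would apply to real sweeps.

## Known limitations

* Single recording channel; no NWB/HDF5 or vendor binary support (the ABF
  format would sit behind the same `recording()` contract as an optional
  adapter).
* No filtering or denoising pipeline, and no spike sorting; the slope
  measurement's smoothing is used only to locate the fit region.
* The broadness criterion assumes fEPSP rise times well above the sample
  interval; waveforms as sharp as ~0.3 ms would be rejected as spikes.
* Facilitation is a single-interval kernel (depends on the previous pulse
  only) and summation is linear; real bursts show sublinear summation and
  short-term depression components.
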