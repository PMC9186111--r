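---
title: "Surrogate methods for parallel spike trains: models, distortions, and the pattern-spectrum test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate methods for parallel spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesurr)
library(dplyr)
```

## The problem

Repeating spatiotemporal spike patterns — specific neurons firing in a
specific temporal arrangement with millisecond precision — can only be called
significant relative to a null model in which such coordination is absent but
everything else about the data (firing-rate modulations, interval statistics,
refractoriness) is retained. For parallel spike-train recordings there is no
tractable analytical null, so the null distribution is built from *surrogate
data*: perturbed copies of the recording that destroy fine-temporal
coordination across neurons while preserving each train's own statistics as
far as possible.

`spikesurr` implements six such surrogate generators, the renewal
point-process models used to benchmark them, a battery of statistics that
quantify exactly *what* each surrogate distorts, and a surrogate-based
significance test for spike patterns (binarization, frequent-itemset mining
over sliding context windows, a 3-d pattern spectrum over signatures, a
surrogate p-value spectrum, and Benjamini–Hochberg-corrected pattern
spectrum filtering).

All user-facing functions take a long-format tibble of spikes
(`trial_id`, `unit_id`, `time_ms`, with the observation interval
`[t_start, t_stop)` carried as attributes) and return tibbles, so analyses
compose with the pipe.

## Spike-train models

Three stationary renewal models serve as ground truth:

* **Poisson** — exponential intervals, CV = 1; the memoryless reference.
* **Poisson with dead-time (PPD)** — no interval shorter than a dead-time
  `d` (1–2 ms in cortical recordings, largely an artifact of spike sorting,
  which cannot resolve overlapping waveforms). Stationary trains draw
  intervals as `d + Exp(λ*)` with `λ* = λ/(1 − λd)`, so the long-run rate is
  exactly `λ`.
* **Gamma** — shape `γ` controls regularity via `CV = 1/√γ`; `γ > 1` is
  regular, `γ = 1` Poisson. Shapes below 1 (bursty) are accepted for
  diagnostics such as the CV map, but the regular regime is the primary use
  case.

Nonstationary variants take a sampled rate profile `λ(t)`. Poisson and PPD
trains are generated at the temporal maximum rate and *thinned* (a spike at
`t` survives with probability `λ(t)/λ_max`); note that thinning a dead-time
process is the literal benchmark construction, not an exact inhomogeneous-PPD
sampler. Gamma trains are generated as a unit-rate renewal process in
*operational time* `Λ(t) = ∫λ` and mapped back through the inverse of `Λ`
(monotone linear interpolation on the profile grid).

Two numerical choices matter here:

* **Equilibrium start.** Renewal generators start the process about ten mean
  intervals before the observation window and discard the prefix. A process
  started *at* the window edge ("ordinary" renewal start) undershoots the
  target rate by up to `(1 − CV²)/2` expected spikes near the start, which
  visibly biases short-trial experiments such as the 150 ms rate-step PSTH.
  With the equilibrium start, window counts equal `∫λ` to Monte-Carlo
  accuracy.
* **Rate estimation.** `estimate_rate_profile()` is a fixed-bandwidth
  Gaussian kernel estimator (default sd 50 ms) with edge renormalization, so
  the profile integral matches the mean spike count per trial. Optimized
  bandwidth selection is deliberately out of scope.

## The six surrogates

All methods share the dither half-width `Δ` (`dither_ms`, default 25 ms):
coordination at timescales below `Δ` is destroyed, structure at coarser
timescales survives.

| method | call | preserves | distorts |
|---|---|---|---|
| UD | `surrogate_uniform_dither()` | count, coarse rate | ISI distribution, dead-time, regularity |
| UDD | `surrogate_udd()` | count, dead-time | regularity, autocorrelation |
| JISI-D | `surrogate_isi_dither(mode="jisi")` | count, joint-ISI distribution, dead-time | autocorrelation mildly |
| ISI-D | `surrogate_isi_dither(mode="isi")` | count, marginal ISI distribution, dead-time | ISI sequence correlations |
| TR-SHIFT | `surrogate_trial_shift()` | everything within a trial | across-trial alignment only |
| WIN-SHUFF | `surrogate_window_shuffle()` | binned count per window | rate profile inside the window |

Implementation decisions that were genuinely open:

* **UD boundary handling.** Displacements that would leave
  `[t_start, t_stop)` are redrawn (default), which preserves the count
  without distorting the displacement distribution; clipping and discarding
  are available behind the `boundary` flag.
* **UDD reference frame.** Spikes are processed left to right against the
  *already dithered* predecessor and the *original* successor, which
  guarantees a feasible window in one pass. An empty window leaves the spike
  in place; the count of such spikes is attached as `n_stuck`.
* **JISI-D/ISI-D.** The joint histogram of (preceding ISI, following ISI)
  pairs is built at 1 ms resolution, truncated at 250 ms (longer intervals
  share the top bin), and smoothed with an isotropic Gaussian of sd 2 ms —
  "of the order of milliseconds"; smoothing is what makes the method usable
  on short recordings. After smoothing, the mass below the unit's minimal
  observed ISI is removed on both axes (`cutoff = TRUE`), so sampled
  intervals never undercut the estimated dead-time. Each spike is then
  redrawn along the anti-diagonal (preserving the sum of its two adjacent
  intervals) by inverse CDF on the discretized conditional, sequentially
  against the dithered predecessor. This sequential-plus-cutoff construction
  is what makes the method order- and dead-time-preserving; dithering
  between the original neighbors, a naive reading of the anti-diagonal idea,
  preserves neither.
* **TR-SHIFT wrap.** Each (unit, trial) train is rigidly shifted by one
  `U[−Δ, Δ]` draw; spikes crossing a trial boundary wrap circularly, which
  preserves the count exactly. The wrap can merge the two boundary gaps of a
  trial into one new interval, so on dead-time input a sub-dead-time interval
  can appear at most once per train (about 0.5% of trains at 60 Hz with
  100 ms segments); `wrap = FALSE` drops border spikes instead and is
  strictly dead-time-preserving. Segment length matters for regularity
  statistics: the statistics suite uses 500 ms (trial-epoch scale) so wrap
  junctions are a negligible fraction of intervals, while the
  p-value-spectrum experiment cuts 2 s trains into the stated 100 ms
  segments.
* **Seeding.** `make_surrogates()` derives one sub-seed per surrogate from
  the master seed, so surrogate `r` can be regenerated in isolation and the
  stream is bit-for-bit reproducible.

## What each surrogate does to the statistics

`run_statistics_suite()` reproduces the diagnostic battery: ISI histograms,
original-vs-surrogate cross-correlograms, auto-correlograms, the CV map, the
moved-spike ratio, and the rate-step PSTH. At full scale (500,000 spikes per
train, 10,000 step realizations) it takes tens of minutes; the same code runs
at any scale.

```{r stats-suite, eval = FALSE}
suite <- run_statistics_suite(n_spikes = 5e5, seed = 1)
plot_cv_map(suite$cv_map)
plot_moved_ratio(suite$moved)
```

The headline effects, all covered by tests at reduced scale:

* UD fills the sub-dead-time interval range and inflates the CV of regular
  trains (CV 0.4 becomes roughly 0.75 at 60 Hz); TR-SHIFT is the only method
  with an exact CV identity.
* UD converts a rate step into a linear ramp of width `2Δ` — the step
  convolved with the boxcar dither kernel — while WIN-SHUFF introduces an
  intermediate plateau in the window straddling the step.
* The **moved-spike ratio** (fraction of spikes leaving their 5 ms bin,
  with per-bin *unclipped* counts matched by `Σ min(c_orig, c_surr)` so that
  swapped spikes count as not moved) falls with firing rate. The constrained
  dithers (UDD, JISI-D, ISI-D) leave almost half of all spikes in place at
  100 Hz; the unconstrained methods (UD, TR-SHIFT, WIN-SHUFF) track the
  two-independent-realizations baseline more closely, with a deficit of
  roughly 8 percentage points at 10 Hz shrinking to ~4 at 100 Hz (mean ~6).

## Spike loss under binarization

Pattern mining binarizes the data: spikes are counted in half-open bins of
width `b` (a spike on a boundary belongs to the right bin; a trailing partial
bin is dropped with a warning) and counts are clipped to 0/1. Clipping
destroys spikes: for a stationary Poisson process the expected loss is

`1 − N_clip/N = 1 − (1 − e^{−λb})/(λb)`,

about 21.3% at 100 Hz with 5 ms bins (`analytic_poisson_reduction()`).
Dead-time and regularity protect against the loss, which is why UD is
dangerous: it turns a regular or dead-time train into a more Poisson-like
one *before* binarization, so the surrogate loses more spikes than the
original data. `expected_spike_count_reduction()` provides the closed form
for Poisson and a Monte-Carlo estimate (with its standard error) for PPD and
Gamma models with or without a surrogate; `run_spike_loss_experiment()`
tabulates the loss-vs-rate curves.

## The pattern-spectrum test

`pattern_spectrum()` slides a `window_bins`-wide context window over every
start bin of the binarized data; each window position is a transaction of
items (unit, lag in bins). Patterns are itemsets containing at least one
lag-0 item, with signature `(z, c, d)` = (size, number of window positions
containing the pattern, maximal lag). Occurrences are anchored at the
lag-0 bin, so every spatiotemporal occurrence is counted exactly once;
overlapping occurrences all count. Windows that do not fit before the end of
a trial are not started, and the convention is identical for original and
surrogate data, which is what the relative comparison requires.

`pvalue_spectrum()` estimates `p(z, c, d)` — the probability under the
surrogate null of seeing at least one pattern with size ≥ `z` and count ≥
`c` at duration exactly `d` — by mining each of `R` surrogates, binarizing
its spectrum, cumulating over the partial order in size and occurrences, and
averaging. With `R` surrogates the smallest nonzero p-value is `1/R`; an
entry of 0 means "below 1/R". `psf()` then tests the occupied signatures:
the number of tests equals the number of occupied `(z, c, d)` with
`(z, c+1, d)` unoccupied (testing a signature implies all smaller ones), the
Benjamini–Hochberg procedure runs at level `alpha` over exactly that set,
and every occupied signature at or below the resulting threshold is
significant together with the patterns carrying it. Patterns with fewer than
`min_occ` occurrences (`min_occ_default()`: at least 10, and at least 30% of
the trial count) are never mined or tested.

Two implementation notes:

* For mining restricted to size 3 (the default for the experiments), an
  exhaustive C++ triplet counter enumerates *all* size-3 itemsets rather
  than closed ones. Closure matters for cataloguing patterns, not for the
  per-duration maximal support that the p-value cumulation consumes, and a
  closure event that would change a null pattern's duration is vanishingly
  rare; the general R miner (`mine_patterns()`) does closed-itemset search
  and is checked against a brute-force enumerator over randomized instances.
* Pattern set reduction (conditional post-filtering of overlapping
  significant patterns) is intentionally absent; the output surface is
  significant signatures plus their patterns after PSF.

### Why the surrogate choice matters

`run_pvalue_spectrum_experiment()` builds averaged p-value spectra for
independent stationary PPD populations (20 units, 2 s, 60 Hz, dead-time
1.6 ms, 5 ms bins, size-3 patterns up to 12 bins duration) under UD and
under TR-SHIFT on 100 ms segments. Because UD surrogates lose spikes to
binarization that the original data keep, fewer occurrences suffice for
significance under UD: at duration 4 bins the BH-corrected minimal
significant count is about 25 under UD versus about 28 under TR-SHIFT — a
systematic liberal bias of the UD null. The desk-scale default is 500
surrogates per spectrum and 20 realizations (about six minutes); the
in-suite check runs 150 surrogates and 4 realizations per seed and asserts
the strict ordering for every seed.

### False positives on nonstationary data

`run_fp_study()` assembles independent nonstationary populations
(`simulate_fp_population()`): one band-limited random rate profile per unit
(low-frequency cosine mixture in a 10–70 Hz band, emulating slow
experimental rate modulations), repeated over 36 trials of 500 ms, from PPD
(dead-times 1.2–2 ms) or Gamma (CVs 0.5–0.85) models. Since units are
independent, every significant pattern is a false positive. At desk scale
(one dataset per model, 100 surrogates) uniform dithering produces on the
order of a hundred false positives pooled over both models while every
other method stays in the single digits, UDD being the runner-up on Gamma
data — the qualitative fingerprint that disqualifies UD. Absolute counts
depend on population size and surrogate count and are not comparable across
scales; only the ordering is a stable claim.

The units involved in false positives concentrate at rates above 20 Hz and
CV2 below 1: high-rate, regular units are where binarization loss under UD
is largest.

## What the synthetic data do and do not show

The generators emulate the features that drive the spike-loss mechanism —
rate modulations on the ~100 ms-and-slower timescale, dead-times, and
renewal regularity. They do not emulate cross-neuron rate co-modulation from
shared behavioral state, non-renewal interval sequences (e.g. serial ISI
correlations beyond the joint-ISI pair), electrode artifacts, or unit
instability. A surrogate method that passes every test here can therefore
still misbehave on real recordings whose violations of the renewal
assumption are strong; conversely the UD failure mode demonstrated here is a
lower bound on the trouble it causes in richer data.

## Problem sizes used by the test-suite and reproduction script

Simulated sizes were chosen so every quantity is estimated with a
Monte-Carlo error well below its assertion tolerance: long stationary trains
use 10⁵–5×10⁵ expected spikes; the p-value-spectrum experiment uses 20
realizations × 500 surrogates in the reproduction script and 4 × 150 per
seed in the test-suite; the calibration check uses 100 independent
populations with 100 surrogates each; the false-positive study uses one
dataset per model with 100 surrogates. All experiments expose their scale
knobs and record them in their reports.

## Known limitations

* The exhaustive triplet engine is quadratic in `units × window_bins` per
  anchor and keeps a 16-bit support slab; it rejects problems beyond ~60,000
  window positions or a few hundred unit-lag items. The R miner has no such
  limits but is meant for small instances.
* The moved-spike ratio's min-count matching is an upper bound on spike
  identity preservation; it cannot distinguish a spike that stayed from a
  different spike entering its bin.
* Thinned nonstationary PPD is faithful to the benchmark construction but is
  not an exact inhomogeneous dead-time process.
* JISI-D/ISI-D require enough intervals to populate a histogram (default
  minimum 50); short sparse trains should use ISI-D or a larger smoothing
  width, and the error message says so.
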