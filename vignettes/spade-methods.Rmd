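---
title: "Detecting spatio-temporal spike patterns: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatio-temporal spike patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Massively parallel spike train recordings (a hundred or more simultaneously
recorded neurons) may contain *spatio-temporal patterns* (STPs): sequences of
spikes from a fixed group of neurons with fixed, millisecond-precise
inter-spike lags that repeat more often than independent firing would
produce. Such patterns are the expected signature of synfire chains, synfire
braids and related assembly models. Two obstacles make their detection hard:
the number of candidate patterns is combinatorially enormous (neurons ×
sizes × lag configurations), and testing each candidate individually creates
an unmanageable multiple-testing problem. This package addresses both with a
mining stage that enumerates only *closed, frequent* candidates and two
alternative statistical stages that separate genuine patterns from chance
ones.

## From spike trains to a formal context

Spike times (ms) are discretized into bins of width `dt` (default 1 ms,
chosen so a neuron rarely fires twice per bin; duplicates clip to one and
the clip count is recorded). A window of `K` bins (default 50, an upper
bound on the pattern duration) slides over the binned data in single-bin
steps. Each window is an *object*; each pair (neuron, within-window offset)
is an *attribute*; a window carries an attribute exactly when the
corresponding spike exists. This re-encoding ("attribute scaling") makes an
STP — a set of spikes with fixed lags — a plain attribute set that repeats
across windows, so ordinary closed-itemset machinery applies. A *formal
concept* is a pair (extent `A` = windows, intent `B` = attributes) each
maximal given the other; its *signature* is `(z, c)` = (pattern size,
occurrence count).

Design choices here, where the construction is genuinely open:

* **Window census.** Windows start at *every* bin (`pad = TRUE`), with
  positions beyond the recording reading as empty, so an occurrence starting
  in the last `K - 1` bins still has a canonical window. The truncating
  alternative (`pad = FALSE`, `n_bins - K + 1` windows) is available; counts
  of chance patterns are mildly sensitive to this choice because they grow
  steeply with the number of windows.
* **Bin convention.** Bins are half-open `[k dt, (k+1) dt)` and assignment is
  floor-based.
* **Shift equivalence.** One recurring spike structure surfaces as several
  concepts: complete time-shifted copies, and window-edge views in which
  leading or trailing spikes have slipped outside the window. The class is
  represented by the pattern whose first spike falls into the first window
  bin; complete copies and leading-edge views fail that rule directly, and
  trailing-edge views are removed by extent matching (a concept whose extent
  is an exact forward shift of a larger concept's extent and whose intent is
  that concept's window-truncated restriction). Without the last rule, an
  injected 10-spike chain would be reported ~8 additional times as its own
  suffixes, each with near-maximal stability.

## Mining closed frequent patterns

`mine_closed_frequent()` is a native depth-first closed-itemset enumerator
(prefix-preserving closure extension with occurrence deliver and conditional
projections). Its contract — exactly the closed itemsets with support ≥
`min_support` and size ≥ `min_size`, with full extents — is pinned down by
`brute_force_closed()`, an independent oracle that closes every object
subset; the test suite checks equality on randomized small contexts. The
default two-stage configuration (mine at support 2, then reject patterns
with fewer than 3 spikes or 3 occurrences) can be collapsed into a
single-stage 3/3 mine, which provably yields the same final set and is what
the pipeline uses; the identity is also tested.

## Stability filtering

The *intensional stability* of a concept `(A, B)` is the fraction of subsets
`C ⊆ A` with `C′ = B`: how reliably the pattern is recovered from partial
occurrence sets. *Extensional stability* swaps the roles (subsets of `B`,
derived window sets compared with `A`) and is sensitive to pattern size
rather than count. Chance concepts have low stability in both senses.

* **Monte-Carlo approximation.** Exact stability enumerates `2^|A|` subsets.
  The approximation draws `Z` subsets uniformly from the power set (each
  element kept with probability 1/2; `Z = 500` by default) and divides by
  `Z`. Whenever `2^|base| ≤ Z` all subsets are enumerated instead, so small
  concepts — the overwhelming majority — get the exact value with zero
  error. This matches the observation that at `Z = 500` over 99% of concepts
  show no approximation error at all, which the test suite reproduces on a
  20-neuron, 15 Hz, 1 s simulation with an injected 8-spike chain.
* **Thresholds from surrogates.** The null distribution of stability under
  independence is estimated by dithering the data (each spike displaced
  uniformly within ±5 ms, redrawn at the boundaries so counts are
  conserved), mining the surrogate and computing stabilities of its
  (filtered, canonical) concepts. The threshold is the upper empirical
  quantile at the Bonferroni-corrected level `alpha / (f × n)` (factor
  `f = 2` when both stability kinds are tested), with a conservative
  ceiling-rank convention: `k = max(1, floor(level × n))`-th largest value.
  At realistic sizes the corrected level is below `1/n`, so the threshold is
  the null maximum — and the false-positive rate of the filter on fresh
  independent data is then the order statistic `1/(n_pool + 1)` per test.
  For that reason the pooled null should be comparable in size to ~100 data
  sets' worth of chance patterns; the package pools `n_surrogates` dithered
  surrogates (default 1 for quick exploration; the validation experiments
  use 100). Filtering is strict (`σ > θ`); the combined mode keeps a concept
  if either measure exceeds its threshold.

## Significance filtering (PSF + PSR)

*Pattern spectrum filtering* estimates, for each signature `(z, c)`, the
probability under independence that some closed frequent pattern with that
signature exists: the fraction of dithered surrogates containing one. In the
default cumulative counting a surrogate pattern `(z, c′)` instantiates every
`(z, c ≤ c′)`, making p-values monotone in `c`; the literal exact-signature
counting is available behind a flag. Distinct signatures present in the data
(not patterns) are tested with Benjamini–Hochberg FDR control at `alpha`,
and all patterns with significant signatures are kept. Signatures never seen
in any surrogate have `p = 0` with resolution floor `1/n_surrogates`; human
readable reports print them as `< 1/n_surrogates`.

*Pattern set reduction* then removes patterns explained by overlap of a real
pattern with background spikes. Every overlapping pair of survivors is
re-tested conditionally: a superset `A` of `B` at signature
`(z_A − z_B + h, c_A)`, the subset at `(z_B, c_B − c_A + k)`, with the
validated corrections `h = 0`, `k = 2`; partial overlaps condition both
sides on the maximal shift-aligned intersection. Because patterns are stored
canonically (lags normalized to start at 0), overlap is computed by aligning
one pattern against the other over all relative shifts — the deterministic
translation of itemset intersection to canonical representatives. Conditional
signatures that fall below the mined domain (`z < 3` or `c < 3`) are treated
as non-significant and noted. If both conditional tests fail, the pattern
covering more spikes (larger `z × c`; ties: larger `z`, then the
lexicographically smaller pattern) is kept. Removals are collected in a
single pass over all pairs and applied at the end, which makes the outcome
independent of pair order.

PSF/PSR significance lookups reuse the realized Benjamini–Hochberg cutoff
from the original data (the corrected significance map), not the raw
`alpha`.

## Synthetic ground truth

`generate_background()` simulates independent Poisson spike trains with four
piecewise-constant rate models: stationary (15/20/25 Hz presets), a coherent
rate step (10 Hz, with 60 Hz on 600–700 ms), across-neuron heterogeneity
(5 Hz rising in 0.2 Hz steps), and a propagating rate jump (20 groups of 5
neurons, 14→100 Hz for 5 ms in sequence, onsets at 50 and 550 ms). Sampling
is exact for piecewise-constant rates (Poisson counts per segment, uniform
placement). `inject_stp()` adds a ground-truth chain: `z` spikes on `z`
neurons at a constant 5 ms lag, at `c` uniformly drawn onsets constrained so
every occurrence fits the recording; overlapping occurrences are permitted.
The generator emulates rate statistics and ground-truth patterns, not
refractoriness, burstiness, gamma-renewal regularity or correlated noise —
passing tests therefore demonstrate correct behavior for independent
(in)homogeneous Poisson backgrounds, and say nothing about non-Poisson
violations of the null.

Scoring is strict: a detection is a true positive only if its (neuron, lag)
composition equals the injected pattern exactly (optionally also covering
every injected onset); any other detection is a false positive.

## Problem sizes used by the automated tests

The full-scale configuration (100 neurons, 25 Hz, 1 s, 1 ms bins, 50 ms
windows, `Z = 500`, 100 realizations, 100 pooled surrogates) is used for the
mining stage counts, the stability thresholds and the type-I experiments in
`scripts/acceptance.R`. The test suite runs the same experiments at desk
scale — 30 neurons for type-I control and stage ordering, 20 realizations
for pattern recovery at full 100-neuron scale — and estimates the null
objects (spectrum, thresholds) once per background model from 100 surrogates
of an independent realization rather than per realization; this is
statistically equivalent for identically distributed realizations and was
chosen to keep the suite fast. The per-realization estimation path is
exercised by the smaller end-to-end tests.

## Numerical and degenerate-input conventions

* All randomness flows through explicit integer seeds; derived sub-seeds
  make surrogate loops order-invariant and each experiment cell
  independently reproducible. Identical seeds give byte-identical JSON
  reports.
* An empty null sample (no chance patterns in the surrogate) yields
  threshold 0 with a warning — any non-trivially stable pattern is then
  retained; fewer than 100 null values warn that the quantile is unreliable.
* Zero-duration simulations, empty spike trains, empty windows and empty
  mining results are all legal and propagate as empty objects.
* `σ = θ` is rejected (strict inequality); `p = α`-boundary signatures are
  kept by Benjamini–Hochberg's `≤` convention.
* R-facing neuron indices are 1-based; serialized artifacts (spike files,
  JSON reports) are 0-based and say so.

## Known limitations

* The miner is exact but single-threaded; spectra over thousands of
  surrogates are embarrassingly parallel across surrogates (seeds are
  per-surrogate) but the package does not itself schedule workers.
* Stability thresholds inherit the variance of an extreme order statistic:
  with Bonferroni correction the threshold is the null maximum, whose value
  moves between the discrete stability atoms (9/16, 19/32, ...) from run to
  run. Counts of near-threshold patterns inherit that volatility.
* Only uniform dithering is implemented as a surrogate; trial shuffling and
  spike-train shifting are out of scope, as are NWB/NEX container formats
  and non-Poisson background models.
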