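---
title: "Models and methods behind amygdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amygdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Primate amygdala neurons respond to facial expressions, and a long-standing
hypothesis holds that a subcortical route (superior colliculus to pulvinar to
amygdala) delivers coarse but fast information about threatening faces,
ahead of the slower cortical route through the temporal lobe.  The
electrophysiological signature of such a route is a *short-latency*,
expression-dependent component in amygdala spiking — roughly 30–80 ms after
stimulus onset, before cortical face processing completes — followed by a
later, sustained, cortex-like component.

`amygdecode` implements the analysis chain used to look for that signature
in trial-aligned spike trains recorded while monkeys viewed 9 face images
(3 identities × 3 expressions: open-mouth/threatening, neutral,
pout-lips/affiliative):

1. **Screening** — which neurons respond to faces at all.
2. **Single-neuron time course** — a sliding-window Friedman test for
   expression sensitivity per neuron, with a shuffle-calibrated count of
   significant neurons over time.
3. **Population decoding** — one-vs-rest linear SVM read-out of expression
   from pseudo-population response vectors per window, with chance
   estimation and ROC/AUC profiling.
4. **Weight analysis** — grouping neurons by the sign of their early-peak
   open-mouth classifier weight (excitation vs suppression), weighted-sum
   and firing-rate time courses, and group response latencies.
5. **Spatial-frequency shift index** — whether a neuron's SF tuning is
   anchored in retinal (cycles/degree, subcortex-like) or image
   (cycles/image, cortex-like) coordinates, correlated with the weights.

Because no recorded dataset ships with the package, a first-class
synthetic-data module generates spike trains with exactly the structure the
analyses assume, so every stage is testable end to end.

## Conventions

* Times are in ms relative to stimulus onset; the epoch is `[-500, 1000)`.
* A window with center $c$ and width $w$ is the half-open interval
  $[c - w/2,\, c + w/2)$, so adjacent non-overlapping windows partition
  time.  The default analysis window is 50 ms wide and slides in 1-ms
  steps; centers below 25 ms span both pre- and post-stimulus periods.
* The "early window" is the 50-ms window centered at 55 ms (30–80 ms),
  motivated by the ~30 ms shortest latency of pulvinar face responses.
* Expressions are ordered `open_mouth`, `neutral`, `pout_lips`; every
  deterministic tie-break (classifier argmax, peak ties) uses this order.

## Nonparametric primitives

The pipeline standardizes on three nonparametric tests, implemented
in-package so that their small-sample behavior is pinned down:

* **Wilcoxon signed rank** (two-sided).  Zero differences are discarded
  (Wilcoxon's original convention, not Pratt's); tied absolute differences
  get mid-ranks.  For n ≤ 25 effective pairs the p-value is exact: the null
  distribution of the positive-rank sum is built by dynamic programming
  over the realized (doubled) mid-ranks, which equals full sign-flip
  enumeration and remains exact under ties.  Beyond 25 a normal
  approximation with tie and continuity corrections is used.
* **Friedman test** with within-block mid-ranks and the standard tie
  correction; a fully tied table yields $\chi^2 = 0$, $p = 1$.
* **Spearman rank correlation** with mid-ranks; exact permutation p-value
  for n ≤ 9 (full enumeration of pairings), t approximation otherwise.

The test suite checks each against an independent brute-force oracle
(sign-flip enumeration, within-block permutation, pairing enumeration) and
against the base-R implementations where those are exact.

AUC is the rank-based Mann–Whitney statistic (ties count half), reflected
about 0.5 when below it, so it measures separation irrespective of sign.

## Single-neuron time course

For each neuron and window, spike counts are arranged into a
blocks × 3-expressions table and tested with the Friedman test (df = 2).
The block construction is under-determined by a design in which each of the
9 images is repeated $n$ times: the default averages counts across the 3
identities within each repetition index, giving $n$ blocks (this matches an
analysis reported with $n = 10$ trials and df = 2); an
`identity_repetition` mode with $3n$ raw-count blocks is available.
Unequal repetition counts are truncated to the per-image minimum in
presentation order, preserving block pairing; neurons under 6 repetitions
are excluded.

False positives for the per-window count of significant neurons are
calibrated by shuffling the stimulus–response relationship: image labels
are permuted across trials *within* each neuron (one permutation per
neuron per shuffle, applied consistently across all windows, preserving
each neuron's count marginal).  The 95th and 99th percentiles of the null
count are computed per window and averaged across windows, since the null
shows no systematic time trend.

## Population decoding

At each window, per-trial spike counts form response vectors
$x \in \mathbb{R}^{N}$.  Counts are normalized within each neuron by its
maximum over the *training fold* (`[0,1,2,3,4]` becomes
`[0, 0.25, 0.5, 0.75, 1]`); normalizing on training data only avoids
leaking test information, and an `"all"` mode reproduces the variant where
the maximum is taken over all trials.  Three soft-margin linear classifiers
$f_k(x) = w_k^\top x + b_k$ are trained one-vs-rest with LIBSVM (C-SVC,
linear kernel, cost 0.125, via `e1071`); the predicted expression maximizes
$f_k$.

Cross-validation follows the repeated random-split reading: in each of 100
simulations, 8 of 10 trials per image are drawn for training (72 vectors)
and 2 for testing (18 vectors), independently per neuron.  Neurons were not
recorded simultaneously, so the pairing of trials into pseudo-trials is
arbitrary; it is re-randomized every simulation, which also means decoding
cannot exploit noise correlations.  An exact 5-fold mode is available.
Chance is estimated by the same machinery after permuting image labels
within each neuron (fresh permutation per simulation).  Note that with only
10 trials per image the *unshuffled* accuracy at signal-free windows has a
large across-dataset variance (a single dataset can sit several SEM from
1/3); the per-simulation re-shuffling is what makes the chance curve tight.

Per-expression accuracies are the correct fractions among each expression's
6 test vectors; pairwise AUCs compare the per-simulation correct-rate
distributions of two expressions, reflected to ≥ 0.5.

## Peaks, weights and latency

`find_peaks_and_trough()` defines the global peak as the curve maximum
(later one under ties), the early peak as the highest local maximum before
it that is separated from it by a local minimum, and the trough as the
lowest point between them.  Raw accuracy curves wiggle by about ±0.02
between neighboring windows at 100 simulations, which creates spurious
local extrema; the pipeline therefore smooths with a 5-center running mean
and requires a 0.02 trough depth before accepting an early-peak candidate.
Both knobs default *off* in the bare function.

Weights for the excitation/suppression analysis come from the open-mouth
classifier at the early-peak window, averaged across the 100 simulations
(simulations in which a neuron was not subsampled do not enter its mean).
Neurons are grouped by weight sign; an exactly zero mean weight is
excluded.  The weighted-sum time courses keep these early-peak weights
*fixed* and probe them at every window — the alternative (per-window
retrained weights) is a config option, but the fixed-weight reading matches
the interpretation that the early mechanism is transient and loses its
effect later.  For these deterministic curves each neuron's per-window
normalization uses its maximum over all trials.

Group latency compares, at each window, the per-neuron mean firing rates
(open-mouth trials) against the same neurons' prestimulus `[-50, 0)` rates
with the paired signed-rank test; the latency is the first window center
with p < 0.05.  A sustained-crossing variant (require k consecutive
significant centers) is available.  Latency searches start at center 25 ms,
the first window fully inside the post-stimulus period.  Note the
irreducible property of a first-crossing definition: any group faces a
~5% per-effective-window chance of a spurious crossing under the null, so
latencies carry that false-start risk.

## Spatial-frequency shift index

For 35-image tuning surfaces (7 center SFs × 5 sizes, fixed 500-ms response
window), the preferred image-based SF at each size is the peak of a
Gaussian in $\log_2$ SF fitted by least squares (`minpack.lm::nlsLM`),
falling back to the grid argmax if the fit fails, and clamped to the tested
span [2, 16] cycles/image to avoid extrapolation.  The **shift index** is
defined here as the least-squares slope of $\log_2(\text{preferred SF})$ on
$\log_2(\text{size})$ across sizes with a defined preference (≥ 3 of 5
required).  This is a re-specification of an index introduced elsewhere,
pinned to the properties that matter: 1 for retina-based tuning (preferred
image SF proportional to size), 0 for image-based tuning (constant), values
above 1 for super-proportional shifts and negative values for opposite
shifts.  The test suite verifies exact recovery of generative exponents
{−1, 0, 0.5, 1, 1.5} on noiseless surfaces.

## The synthetic-data generator

`simulate_population()` draws every trial from an inhomogeneous Poisson
process: rate profiles are piecewise constant at 1-ms resolution, each 1-ms
bin gets a Poisson count, and spikes are placed uniformly within their bin.
This is exact for piecewise-constant rates and simpler than thinning.
Profiles sum a baseline, an early transient component (excitatory or
suppressive, expression-dependent) and a late sustained component with an
optional linear rise, clipped at zero and scaled by a per-identity gain
drawn once per neuron from a narrow log-normal (identities modulate rates
without carrying expression information).

The default preset encodes the population structure the analyses are built
to detect, with 10 trials per image:

| group | n | baseline | early component | late component |
|---|---|---|---|---|
| positive (early-excited) | 20 | 10 sp/s | +15 open-mouth, +6 others, 40–80 ms | +6 all, onset 90 ms, 100-ms ramp |
| negative (early-suppressed) | 20 | 15 sp/s | −12 open-mouth, −3 pout-lips, 0 neutral, 50–80 ms | +22 neutral, +8 open-mouth, +6 pout-lips, onset 90 ms, 100-ms ramp |
| nonselective | 60 | 10 sp/s | — | — |

Rationale for the numbers, chosen once from power considerations:

* Amplitudes are not reported quantities for any recorded neuron; they are
  assumptions.  They are sized so that (i) a 50-ms window at 10 trials per
  image gives the early open-mouth signal high single-neuron Friedman power
  at the early window while prestimulus windows stay null; (ii) suppression
  is salient relative to Poisson count noise, so the SVM reliably assigns
  suppressed neurons negative open-mouth weights; and (iii) the late
  neutral-preferring rebound dominates the decoding curve, so the global
  accuracy peak is late, as in the narrative the generator emulates.
* Suppression onset is 50 ms, 10 ms after the excitation onset:
  feedforward/local inhibition lags the excitation that drives it.
* The late component ramps over 100 ms because a step onset at 90 ms
  right after the early offset at 80 ms leaves no window in which signal is
  weak — the decoding curve would have no trough.  A gradual build-up of
  the sustained, cortex-like component is also the natural physiological
  shape.
* Per-neuron amplitude heterogeneity (×0.75–1.25) and per-identity gains
  (log-normal, sdlog 0.1) add realism without changing the group-level
  structure.

What the generator deliberately does **not** emulate: noise correlations
(the decoding design discards them anyway), refractory periods, bursting,
spike-sorting contamination, drifting baselines, and aborted trials.
Passing tests on this generator therefore demonstrate that the *pipeline*
recovers the structure it targets under Poisson variability — not that
real amygdala data contain that structure.

## Problem sizes in the test and acceptance runs

The packaged checks run on desk-scale problem sizes chosen as package
defaults: null calibration uses 104 flat-rate neurons, windows every 25 ms
from −100 to 500 ms and 200 label shuffles; decoding time courses use
windows every 10 ms from 25 to 250 ms at 100 simulations per window;
latency ordering uses 20 independently seeded populations with 1-ms window
steps from 25 to 150 ms.  The same functions run unchanged at the full
1-ms/1000-shuffle resolution.

## Known limitations

* The exact signed-rank path enumerates up to n = 25; group latency on
  much larger groups switches to the corrected normal approximation.
* The Friedman p-value is the tie-corrected chi-square approximation;
  for very few blocks its exact permutation null is coarser (the test
  suite bounds the discrepancy).
* Pseudo-population decoding with 10 trials per image has heavy
  across-dataset variance at signal-free windows; single-dataset accuracy
  values there should be read against the shuffle-based chance curve, not
  against 1/3.
* `run_pipeline()`'s SF stage simulates tuning surfaces aligned with the
  generator's group labels (retina-based for early-excited neurons,
  image-based otherwise); with real data you would instead supply measured
  surfaces to `shift_indices()`.
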