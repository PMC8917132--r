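---
title: "Models and methods behind rippletiming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rippletiming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippletiming)
```

## The scientific question

During rest and sleep, hippocampal CA1 emits sharp-wave ripples (SWRs):
~50-150 ms bursts of 100-250 Hz oscillation during which pyramidal cells
fire time-compressed spike sequences. What sets the millisecond-scale
timing of each cell's spikes within a ripple? One candidate mechanism is
inhibition arriving *before* ripple onset: if a pyramidal cell is
transiently hyperpolarized in the tens of milliseconds preceding the
ripple, its depolarization during the ripple peaks later and its first
spike is delayed. `rippletiming` implements the full analysis chain by
which that hypothesis can be tested: ripple detection, intracellular
membrane-potential (Vm) quantification, spike-latency statistics keyed
to interneuron pre-ripple firing, and two latent-variable models of
population spike counts — a Poisson-emission hidden Markov model for
within-ripple sequences and a Poisson mixture for across-ripple
interneuron ensembles.

All recorded inputs are replaced by seeded generators
(`gen_lfp`, `gen_vm`, `gen_unit_spikes`, `gen_hmm_counts`,
`gen_mixture_counts`) that inject each effect with known magnitude, so
every stage is testable against ground truth without any download.

The package is organised as a conventional R package whose functions
carry all computation; the numbered scripts under `analysis/` are thin
narrative drivers that run a synthetic session end to end and write
tables under `results/`. There is deliberately no shell-level command
line tool: the functions and scripts are the interface.

## Conventions

Time is seconds (float64) everywhere internally; milliseconds appear
only in arguments whose conventional units are ms (bin widths, windows,
latencies). Sample indices are 0-based in the time arithmetic
(`t = t0 + k/rate`) and event intervals are half-open `[onset, offset)`.
Continuous traces travel as flat little-endian float32 plus a JSON
sidecar; events and spikes as headered CSV.

## SWR detection

Two detectors are implemented, mirroring the two acquisition pathways.

**Patch-clamp sessions** (`detect_swr_patch`): the LFP is band-passed
100-250 Hz (zero-phase type-I Chebyshev, 1 dB ripple, order 4), and a
smoothed rectified envelope (8-ms moving average) is thresholded at
3 x SD of the baseline noise. "Baseline noise" is estimated robustly:
the scaled median absolute deviation of the filtered trace, re-estimated
once with detected events (dilated by 100 ms) excluded, so the ripples
themselves cannot inflate the threshold. Because the recipe that pairs a
500 Hz sampling rate with a 100-250 Hz band puts the upper band edge at
Nyquist, this pathway instead works at 1250 Hz, which preserves the
stated band.

**Silicon-probe sessions** (`detect_swr_probe`): the signal is
downsampled to 1250 Hz, band-passed 130-200 Hz (fourth-order Chebyshev),
squared, smoothed, and z-scored — the "normalized squared signal". Peaks
are detected at 5 SDs above the mean; each event's start and stop are
the surrounding crossings of 2 SDs; events outside 20-200 ms are
discarded, as are events co-detected on a designated noise channel.

Two normalization details are package design choices. First, the mean
and SD used for z-scoring are re-estimated iteratively with
suprathreshold stretches excluded. On a long in vivo session ripples
occupy ~1-3% of the record and barely perturb the global SD, but any
record with a higher ripple duty cycle (including compact synthetic
sessions) inflates the SD several-fold, which silently converts "2 SDs"
into a much higher absolute threshold and biases onsets late by tens of
milliseconds. Excluding detected events recovers the noise-referenced
meaning of the thresholds regardless of ripple density. Second,
detection and boundary placement use two smoothing scales: a 20-ms
window stabilizes the detection statistic (the squared band-limited
signal has very few effective degrees of freedom per sample, so short
windows produce spurious 5-SD peaks), while a 4-ms window localizes the
2-SD boundary crossings so that slow envelope fluctuations do not bleed
the boundaries into adjacent noise. With both in place, onset errors on
synthetic Hanning-enveloped bursts at 10x noise SD average ~4-5 ms.
A single-scale 8-ms variant was measured to give either late onsets or
boundary bleed, depending on the normalization; the two-scale form is
the package's resolution of a detail the original description leaves
open. Both detectors are exactly invariant to amplitude rescaling, since
every threshold is SD-relative.

Manual event curation is replaced by `swr_qc`: explicit minimum
ripple-band-power and maximum line-noise rules with logged reason codes.
Sessions with fewer than 30 SWRs are excluded (`require_min_swrs`).

## Intracellular analysis

Spikes are detected as peaks during periods with Vm above -20 mV. For
subthreshold averaging, spikes are truncated: the raw trace is smoothed
with a 1-ms moving average, a leading edge is marked where the rate of
change first exceeds 4 V/s, and samples are linearly interpolated from
the edge until the trace first returns to (or below) the edge value.
Edges that follow within an interpolation segment — complex spikes —
each anchor their own segment at their own edge value; the alternative
reading (anchoring every segment at the first edge) would splice
progressively stale values across a burst and is not used. The operation
is idempotent, and a spike that never returns below its edge value
before the trace ends is truncated to the end with a warning.

Per SWR, the package computes:

* **Baseline Vm** — mean over [-2000, -1000) ms relative to onset.
* **Pre-SWR Vm change** (`compute_delta_vm_pre`) — the minimum Vm in
  [-50, 0) ms is located, Vm is averaged over +/-25 ms around that
  minimum (applied literally even where the window crosses onset into
  the SWR), and the baseline is subtracted. Negative values are
  pre-ripple hyperpolarizations.
* **Depolarization peak time** (`compute_depol_peak`) — the time of the
  Vm maximum in [-20, +120] ms; ties go to the earliest sample.
* Events lacking full coverage are skipped with reason codes, never
  padded, to avoid baseline bias at recording edges.

Clamp currents convert to conductances by
`g(t) = (I(t) - I_baseline) / (V_hold - E_rev)` with the conventional
pairs (-70, 0) mV for excitation and (+10, -90) mV for inhibition; with
current in pA and potentials in mV the quotient is in nS.

Three-cell recordings support a rank-order permutation test
(`triplet_order_test`): among SWRs whose depolarization peaks occur in
cell order 1-2-3, the frequencies of the six possible orders of the
pre-SWR Vm changes are tabulated and compared with a null built from
10,000 within-SWR exchanges of the three values; orders outside the
central 95% permutation band are flagged. Cell pairs support Pearson
correlations of the two per-SWR quantities across shared events, with
two-sided t-tests of the coefficients (`pairwise_vm_correlations`).

## Quintile latency analysis

Interneurons that fire before ripple onset are identified from
peri-event time histograms (2.5-ms bins, [-200, +200] ms window — the
bin width is standard, the span is a package default): cells whose peak
firing time lies more than 1.5 SDs below the population mean peak time.
Each such interneuron's single-trial pre-SWR rate is the mean, over the
30 ms before onset, of its spike train smoothed with a Gaussian kernel
of 15 ms FWHM (sigma ~ 6.37 ms; the kernel integrates to the spike
count). SWRs are ranked by this rate and split into quintiles (Q1
highest; sizes differ by at most one; ties broken by a stable sort so
labels are deterministic).

For each pyramidal cell, first-spike latency is measured from SWR onset
to its first spike within `[onset, offset]` (spikes before onset do not
count), and rank order is its normalized position among all pyramidal
cells participating in that SWR. The latency effect is the difference
in mean latency between Q1 and Q5; significance comes from shuffling
latencies across quintile labels 500 times and asking whether the
observed difference falls outside the null's central 95%. On
exchangeable data the test rejects at the nominal 5% (verified over
1,000 runs in the acceptance suite); with ~5 ms realized gaps at 300
SWRs its power exceeds 80%.

## Poisson-emission HMM for within-SWR sequences

Spikes of N pyramidal cells are binned into nonoverlapping 15-ms bins
per SWR. The network is assumed to occupy one of M latent states per
bin, with first-order Markov transitions (initial distribution `pi`,
transition matrix `A`) and, within a state, independent Poisson spike
counts per cell (expected-count matrix `Lambda`, N x M). Fitting is by
Baum-Welch EM with scaled forward-backward recursions (log-space
emissions, so long sequences cannot underflow); the likelihood is
non-decreasing every iteration, a property asserted to 1e-8 in tests.
Initialization draws `Lambda` from a random hard assignment of bins to
states with jitter, `A` near-uniform with a slight self-transition
bias, and runs 5 restarts by default; `Lambda` is floored at 1e-4
counts/bin to keep log-likelihoods finite on silent cells. Convergence
is a relative log-likelihood change below 1e-6, capped at 500
iterations. The forward-backward likelihood is verified against
exhaustive state-path enumeration on every instance with M in {2,3} and
T up to 6.

For the sequence-similarity question, models are fitted separately to
Q1 and Q5 SWRs and each model scores both groups by mean per-bin
log-likelihood; `LL(test) - LL(train)` below zero means a model captures
its own quintile's sequences better. As a control, SWRs are randomly
reassigned to two groups of the same sizes, models are refitted, and
the differences recomputed; the observed values are compared one-sidedly
against the shuffle distribution. The in vivo standard of M = 15 states
is kept as the default of `fit_poisson_hmm`; the synthetic drivers use
smaller M matched to their session sizes, and `cv_select_states`
provides the twofold cross-validation used to justify such choices.

## Poisson mixture for interneuron ensembles

Across SWRs, the spike-count vector of N interneurons is modeled as a
mixture: each SWR belongs to one of M latent "ensembles" with
probabilities `pi`, and counts are Poisson with ensemble-specific means
(`lambda`, N x M). EM with restarts fits the model; responsibilities
give soft labels, their argmax hard labels.

The number of ensembles is chosen by 20-fold cross-validation: for each
M in a grid (2-30 by default, capped by the training-fold size), the
mean held-out deviance (-2 x log-likelihood) is computed, a
monotonically descending exponential `a exp(-bM) + c` is fitted to the
curve, and the grid value maximizing the curvature
`|d''|/(1 + d'^2)^{3/2}` — the point just before the plateau — is
selected. The exponential is fitted to the deviance curve normalized to
[0, 1]: curvature is not invariant to axis scaling, and raw deviance
magnitude grows with the number of SWRs, so selection on the raw curve
would drift with session size while the normalized curve isolates the
shape. A non-descending or flat curve falls back to the deviance
minimum with a warning.

Goodness of fit is assessed against surrogates in which each
interneuron's counts are permuted across the test fold's SWRs —
destroying co-firing while preserving marginal rates exactly. The same
20-fold CV is run, 50 permutations per fold, giving 1000 log-likelihood
differences (positive when real data beat their surrogates). For the
significance test these values cannot be treated as independent: the 50
repeats within a fold share one model and one test fold, and even
per-fold summaries are positively correlated across folds because each
fold's model is trained on the other folds' test rows (both effects
were measured during development; the naive t-test on the 1000 values
rejects a true null far above its nominal level). The primary p-value
therefore uses a construction with no such leakage: one model is fitted
to half of the folds, each disjoint fold of the held-out half is ranked
within its own permutation orbit — by row exchangeability these
mid-ranks are iid uniform under the null — and the ranks are combined
with Stouffer's method (two-sided). Over 200 structure-free sessions
the resulting p-values are indistinguishable from uniform
(Kolmogorov-Smirnov p = 0.78), while on 3-ensemble data the test
reaches p ~ 1e-13. The fold-mean t-test is still reported as
`p_value_t` for comparison with the conventional procedure.

Ensemble profiles are reported as the `lambda` columns (predicted
counts) and as Z-scores of each interneuron's predicted count against
its across-SWR count distribution; ensemble-ensemble correlations are
computed in both spaces. Raw-space correlations near 1 with Z-space
correlations spread around 0 are the signature of ensembles that
co-fluctuate around shared mean rates rather than partitioning cells.

## What the generators emulate — and what they do not

`gen_lfp` embeds Hanning-enveloped ripple-band sinusoid bursts
(60-120 ms, default 10x noise SD, 150 Hz) in white noise, spaced at
least 500 ms. `gen_vm` builds a Vm trace whose per-SWR hyperpolarization
is a raised-cosine dip of half-width 25 ms with its minimum 25 ms before
onset, scaled so that the +/-25 ms averaging window mean equals the
configured depth — making the measured pre-SWR Vm change analytically
equal to minus the injected depth in the noiseless case; depolarization
is a raised-cosine transient whose peak time is linear in the dip depth
(default -3 ms/mV against the Vm change, i.e. deeper dips push the peak
later), and threshold crossings emit 2-ms triangular spikes to +20 mV,
which exercise the -20 mV detector and the 4 V/s edge logic.
`gen_unit_spikes` emulates the *selected* pre-SWR-firing interneuron
subpopulation: per-SWR pre-onset rates are gamma-distributed with mean
60 Hz and CV 0.6 (a strongly pre-ripple-active cell; at much lower
rates the 30-ms estimation window carries almost no information and the
quintile grouping degenerates to noise), within-SWR interneuron firing
is 30 Hz so the PETH peak falls before onset, and each pyramidal cell's
first-spike latency increases by 0.1 ms per Hz of its paired
interneuron's pre-rate — about a 10 ms injected Q1-Q5 gap — with 5 ms
jitter. `gen_hmm_counts` and `gen_mixture_counts` are exact generative
twins of the two latent-variable models.

Dip magnitudes across SWRs are drawn Gaussian; the source data report
only means and SDs of measured values, so Gaussianity is an assumption
of the generator, not a claim about the recordings. The generators use
white noise (an optional 1/f component is deliberately absent by
default so SD-based thresholds remain analytic), perfectly regular
event spacing where spacing is irrelevant, and one-to-one
interneuron-pyramidal coupling by index. Passing tests therefore
demonstrate correctness of the estimators and calibration of the null
distributions under controlled conditions; they do not demonstrate
robustness to non-stationary baselines, theta-state contamination,
spike-sorting errors, or correlated noise, all of which real sessions
contain.

## Problem sizes and numerical choices

The test and acceptance runs use sessions scaled for a single CPU:
20-30 embedded ripples per detector run, 120-200 SWRs for the Vm
pipeline, 300 SWRs for quintile analyses, 200 sequences (N = 10 cells,
T ~ 8 bins, M = 3) for HMM recovery, and 500 SWRs x 12 interneurons
(true M = 3) for mixture recovery and selection — sizes at which every
recovery criterion has comfortable margin while a full run of suite
plus acceptance script stays in single-digit minutes. Tolerances worth
knowing: the rate floor (1e-4) on all Poisson means; EM convergence at
relative 1e-6 (1e-4 inside cross-validation loops, where the deviance
average is insensitive to the last digits); zero-phase filtering
reproduces linearity to ~1e-8 relative (float roundoff through the
narrow-band recursion), so exactness-style assertions use 1e-6;
tie-breaks (equal extrema, equal rates, equal ranks) always resolve to
the earliest index via stable ordering, making every labeling
deterministic under a fixed seed.

## Known limitations

The probe detector's boundary placement is accurate to ~5 ms on tapered
bursts but an adjacent noise excursion can occasionally extend a
boundary by more; per-event worst-case onset error is not bounded.
The curvature-based ensemble selection inherits the exponential's
rigidity: deviance curves with two elbows resolve to the first. The
cross-quintile HMM comparison refits a model per shuffle and is the
most expensive operation in the package; its defaults (100 shuffles)
assume minutes, not seconds. The interneuron-pairing structure of the
spike generator is the simplest that the quintile analysis can detect;
it does not emulate shared inhibition across multiple pyramidal cells.
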