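# rippletiming

Analysis pipeline for asking how inhibition *preceding* hippocampal
sharp-wave ripples (SWRs) shapes the spike and depolarization timing of
CA1 pyramidal cells. It is written for electrophysiologists working
with paired intracellular/LFP recordings or high-density probe data,
and for methodologists who want tested, seeded implementations of the
statistics involved.

The package implements, as plain R functions:

* **SWR detection** — a 3 × SD filtered-envelope detector for
  patch-clamp sessions and a 5/2 SD normalized-squared-signal detector
  (130–200 Hz, 1250 Hz, 20–200 ms duration limits, optional noise
  channel) for probe sessions, plus rule-based event QC.
* **Intracellular quantification** — spike detection (> −20 mV) and
  truncation (4 V/s leading edge, linear interpolation), the pre-SWR
  membrane-potential change ΔVm_pre (mean over ±25 ms around the Vm
  minimum in the 50 ms before onset, minus the 2–1 s baseline), the
  depolarization peak time (−20…+120 ms window), synaptic conductance
  decomposition g = ΔI/(V_h − E_rev), SWR-triggered averages, pairwise
  correlations, and a 10,000-swap triplet rank-order permutation test.
* **Quintile latency analysis** — Gaussian-kernel (15 ms FWHM) pre-SWR
  interneuron rates in a 30-ms window, quintile grouping of SWRs
  (Q1 = strongest inhibition), pyramidal first-spike latency and rank
  order, and a 500-shuffle significance test for the Q1−Q5 latency gap.
* **Poisson-emission HMM** (Eq.-style model: states `π`, transitions
  `A`, expected counts `Λ`) over 15-ms-binned SWR spike counts, fitted
  by Baum–Welch EM with scaled forward–backward likelihoods, and a
  cross-quintile sequence-similarity test with shuffle controls.
* **Poisson mixture ensembles** over per-SWR interneuron counts:
  EM fitting, 20-fold cross-validated deviance, curvature-based
  selection of the ensemble number, a calibrated surrogate
  (co-firing-destroying) goodness-of-fit test, and Z-scored ensemble
  profiles.
* **Seeded synthetic-data generators** for every input the pipeline
  consumes, with ground truth returned alongside, so the whole chain is
  testable end to end without recorded data.

## Worked example

Simulate a membrane-potential trace in which deeper pre-ripple
hyperpolarizations push the ripple depolarization later, then recover
that coupling with the measurement pipeline:

```r
library(rippletiming)

onsets <- 10 + (0:199) * 4.2
cfg <- vm_gen_config(n_swr = 200, coupling_ms_per_mv = -3, seed = 7)
sim <- gen_vm(cfg, onsets)
events <- event_table(1:200, onsets, onsets + 0.04, onsets + 0.08)

rec <- delta_vm_records(sim$trace, events)
head(rec[, c("swr_id", "delta_vm_pre_mv", "depol_peak_time_ms")], 3)
#>   swr_id delta_vm_pre_mv depol_peak_time_ms
#> 1      1       -2.084975                 59
#> 2      2       -2.209334                 60
#> 3      3       -3.466342                 60

cor.test(rec$delta_vm_pre_mv, rec$depol_peak_time_ms)$estimate
#>        cor 
#> -0.7081086
```

Each row is one SWR: `delta_vm_pre_mv` is the pre-onset
hyperpolarization (negative = hyperpolarized) and
`depol_peak_time_ms` the time of the depolarization maximum after
onset. The strongly negative correlation (here r = −0.71 across 200
events) is the pipeline recovering the injected structure: more
pre-ripple inhibition, later depolarization.

The numbered scripts under `analysis/` run a full synthetic session —
simulation, both detectors, the Vm pipeline, quintile latency tests,
the sequence HMM, and ensemble extraction — and write their tables
under `results/session/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_swr.R   # probe detector: recall 97%, onset error ~4 ms
Rscript analysis/03_vm_analysis.R  # dVm_pre -2.05 ± 0.86 mV, r = -0.70
Rscript analysis/04_quintile_latency.R
Rscript analysis/05_hmm_sequences.R
Rscript analysis/06_ensembles.R    # selects M* = 3 ensembles, surrogate p ≈ 2e-13
```

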