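---
title: "Quantifying stimulus coding in neuronal ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulus coding in neuronal ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeinfo)
```

## The scientific problem

Rodent barrel cortex maps each facial whisker onto one cortical column, and
neurons in a column respond most strongly and earliest to deflections of
their principal whisker (PW), more weakly and ~5 ms later to neighbouring
whiskers (NWs). Given simultaneously recorded spike trains from putative
inhibitory (INH, narrow-spiking) and excitatory (EXC, broad-spiking) neurons
under controlled single-whisker deflections, this package quantifies how
much stimulus identity (which whisker; at which deflection frequency) single
cells and ensembles encode, and how that information is organised: linearly
summed, redundant, or shaped by correlations.

Three complementary measurements are implemented:

1. **Direct information.** Discrete mutual information between stimulus and
   response, `I(S;R) = H(R) - H(R|S)`, computed on per-trial spike counts in
   a post-stimulus window or on binary spike patterns (the window split into
   bins; a bin is 1 when it contains at least one spike). `P(s)` always
   comes from trial counts.
2. **Information breakdown.** Ensemble information decomposed as
   `I = I_lin + I_sig-sim + I_cor-ind + I_cor-dep`, built from the
   conditionally independent surrogate `nu(r|s) = prod_c P(r_c|s)`. The
   linear term sums single-cell informations; the signal-similarity term
   (always <= 0) measures the cost of correlated mean tuning; the two
   correlational terms measure the impact of stimulus-independent and
   stimulus-dependent noise correlations. All terms derive from one set of
   plug-in probabilities, so the identity is exact to machine precision.
3. **Decoding.** Trial-by-trial stimulus prediction with a linear
   discriminant on the first ten principal components of the response
   array, stratified four-way cross-validation (75% train / 25% test per
   fold), transmitted information of the confusion matrix (a lower bound on
   the direct information), and trial-shuffled surrogates that destroy
   noise correlations while preserving per-class marginals exactly.

## Limited-sampling bias correction

Plug-in information is biased upward when the response alphabet is not well
sampled. The default correction is quadratic extrapolation (QE): the
estimate is recomputed on class-stratified disjoint halves and quarters of
the trials, and `I(x) = a + bx + cx^2` (x = inverse data fraction) is solved
through the three points; the intercept `a` is the infinite-data
extrapolation. Partitioning is repeated (default twice) and averaged.
A leave-one-trial-out jackknife is provided as the alternative;
`info_vs_trials()` exposes the decay diagnostic used to verify that the
trial budget suffices. Corrected values may be slightly negative and are
reported unclipped by default, which keeps the estimator unbiased around
zero. Where bias is nonlinear in 1/N — ensembles whose product alphabet
rivals the trial count — no extrapolation is trustworthy; the package
follows the field's practice of capping pattern-based ensemble estimates at
10 neurons and falling back to spike counts beyond that.

## The synthetic-session generator

No recorded data ship with the package; `generate_session()` draws sessions
with the statistical structure the analyses assume, so every stage runs
end-to-end and parameter-recovery tests have ground truth. The generator
emulates, with defaults chosen once from the recorded protocol and response
statistics:

- **Protocol**: per whisker, one low-frequency block of 200 trials with
  irregular 5–30 s intervals, then one 100-trial block per periodic
  frequency (1, 2, 4, 7, 10 Hz) at exact 1/f spacing; blocks separated by
  10 s.
- **Evoked responses**: per neuron and trial,
  `count ~ Poisson(mu * a(trial) * g(trial))`, with `mu` the PW mean count
  (defaults 0.8 spikes/trial for INH, 0.35 for EXC, scaled per layer),
  reduced by `nw_count_ratio` (default 0.5) for first-order neighbouring
  whiskers and zero beyond. Most cells therefore fire under one spike per
  stimulus, the regime the analyses target. Spike times sit at the base
  latency (8 ms for PW, +5 ms for NW) plus half-normal jitter (SD 2 ms INH,
  5 ms EXC), so no evoked spike precedes the stimulus.
- **Adaptation**: `a(trial) = floor + (1 - floor) exp(-(trial-1)/tau)`
  applied only at >= 4 Hz (defaults floor 0.4, tau 7 trials, so the
  20-trial exclusion removes the transient).
- **Shared gain**: `g(trial) = exp(eps)`, `eps ~ N(0, shared_gain_sd)`,
  drawn once per trial and shared by all neurons — the noise-correlation
  knob (default 0: conditionally independent neurons).
- **Population structure**: a 14.2% INH fraction; INH cells all informative
  with PWs assigned round-robin across whiskers (heterogeneous tuning
  templates); 20% of EXC cells informative, sharing the first whisker as
  template by default, with `informative_exc_gain = 2` making this minority
  highly informative; the remaining EXC cells lack PW/NW count contrast
  (ratio 1) but keep the latency offset. Waveform features are drawn from
  two well-separated clusters (trough-to-peak 0.20 +/- 0.02 ms vs 0.41 +/-
  0.02 ms), so the default classification boundary at 0.30 ms recovers the
  generated labels exactly.
- **Spontaneous activity**: homogeneous Poisson over the whole session
  (defaults 5 Hz INH, 1 Hz EXC).

Randomness is organised as per-neuron and per-block sub-streams derived
from the master seed, and cell types cycle deterministically through the
target fractions; enlarging a population therefore never perturbs the
spike trains of existing neurons, and identical seeds give identical
sessions.

What the generator does **not** emulate: membrane or conductance dynamics,
whisker kinematics, within-cell temporal correlations beyond the latency
structure, slow nonstationarities, layer-specific latencies, and
electrode-level artefacts. Tests passing on synthetic sessions demonstrate
that the estimators and pipeline behave correctly under the assumed
statistical structure — not that recorded cortex satisfies that structure.

## Waveform classification

Putative INH/EXC labels come from a configurable linear boundary in the
(trough-to-peak, asymmetry) plane. The published analysis plots its
criteria but does not print the numbers, so the default is a documented
stand-in: a pure trough-to-peak threshold at 0.30 ms (INH below), with the
asymmetry coefficient available as a second boundary term and the boundary
value itself assigned to the broader-spiking majority class. The printed
best-EXC waveform means (0.41 ms, -0.34) classify as EXC under this
default.

## Design choices where the methods were open

- **Pattern bins are binarised** (>= 1 spike -> 1), consistent with
  response-space accounting of at most one spike per bin; raw counts are
  kept separately, and the per-bin maximum matters only in the rare trials
  where two spikes share a 5 ms bin.
- **QE partition scheme**: fractions fixed at {1, 1/2, 1/4} with
  class-stratified random disjoint partitions, two repeats by default; the
  original toolbox's averaging scheme is not documented, so this default is
  stated rather than inherited.
- **Breakdown formulas**: only the top-level identity is printed in the
  methodology this follows; the component definitions used here
  (`I_sig-sim = I_ind - I_lin`, `I_cor-ind = sum_r [P(r) - nu(r)]
  log2(1/nu(r))`, `I_cor-dep` as the exact residual) are fixed as normative
  and verified against an independent direct evaluation of the
  stimulus-dependent term in the tests. Breakdown defaults to spike counts
  in the 50 ms window; the term-wise QE variant preserves the sum identity
  because extrapolation is linear.
- **Noise-correlation averaging** across stimulus classes is weighted by
  class trial counts (unweighted available).
- **Decoding**: folds are class-stratified (required for stable per-class
  estimates); the PCA projection is fitted on training folds only by
  default, with a global-fit option reproducing the literal published
  procedure; the LDA pooled covariance is shrunk toward a scaled identity
  with an analytic (Ledoit-Wolf) intensity because ten-component feature
  spaces from few trials can be ill-conditioned. Performance is reported
  as pooled percent correct over all test trials (per-fold means also
  returned).
- **Comparable groups**: the INH group is the full INH set; the best-EXC
  group is the smallest descending-order prefix whose ensemble information
  reaches the INH total ("at least the same amount" read as >= with an
  optional epsilon). Ensemble-information curves for this comparison use
  spike patterns under the 10-neuron cap — the space in which ensemble
  information and hence the matching criterion is defined — while the
  breakdown terms and pairwise noise correlations use counts.
- **Statistics**: the normality gate (D'Agostino-Pearson omnibus test,
  implemented in-package from the standard Z-approximations) sends a
  comparison to t-tests only when both samples are normal *and* have
  n >= 20; the permutation ANOVA permutes raw observations (the simplest
  scheme consistent with a permutation-based factorial test; residual
  permutation is a known refinement not implemented here), and FDR
  correction is Benjamini-Hochberg by default.

## Directional reproductions and problem sizes

The recorded-data values (e.g. 0.29 bits for L4 INH cells, group
redundancies of -0.29 vs -0.86 bits) are not reproducible without the
recordings; the package instead reproduces their *directions* on synthetic
sessions, at desk scale:

- single-cell information: 30-neuron single-session populations,
  low-frequency blocks, QE on 50 ms / 5 ms patterns; INH exceed EXC in
  granular/infragranular layers in >= 80% of 20 seeds;
- redundancy and signal similarity: 3-whisker sessions (with two whiskers,
  round-robin INH assignment still leaves half the INH pairs sharing a
  template, so the heterogeneous-INH condition needs three), pattern-based
  QE curves for the matched groups, count-based breakdown; best-EXC groups
  come out more negative on both measures;
- shuffle gain: frequency decoding across shared-gain levels {0, 0.5, 1.0}
  and neuronal groups, where the rate signal is common-mode and aligned
  with the shared-gain noise direction; for two-class location decoding
  the discriminant has mixed-sign weights and removing positive noise
  correlations need not help, which is why the frequency scheme is the
  robust carrier of this effect.

These sizes (20 seeds, 24–30 neurons, 200-trial low-frequency blocks) are
the package's chosen desk-scale study conditions; they keep the full test
suite within a few minutes while leaving each directional effect clearly
resolved.

## A worked run

```{r example, eval = FALSE}
cfg <- synth_config(n_neurons = 24, seed = 42)
out <- generate_session(cfg)
tensor <- build_responses(out$session,
                          block_ids = out$session$blocks$block_id[
                            out$session$blocks$frequency_class == "<1"])
single_cell_info(out$session, tensor, seed = 1)
report <- run_full_analysis(cfg, estimator = "qe", seed = 42)
report$by_group
autoplot(report$curves$mi_descending)
```

## Known limitations

- Plug-in and even QE-corrected estimates remain biased when the response
  alphabet is comparable to the trial count; the stimulus-dependent
  correlational term inherits this bias most strongly. Keep ensembles
  small (<= 10 neurons) or use counts.
- The permutation ANOVA's unrestricted permutation scheme tests the joint
  null for the interaction term; effects confined to the interaction in
  the presence of strong main effects are better served by residual
  permutation.
- The generator's Poisson evoked-count model has no refractoriness or
  burst structure; latency codes richer than a single jittered first-spike
  volley are out of scope.
- `spontaneous_rate()` treats the recording as starting at time zero;
  sessions whose first event starts much later should set `duration_s`
  explicitly.
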