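# spikeinfo

Information-theoretic analysis of stimulus coding in simultaneously
recorded neuronal ensembles, built around the whisker-deflection paradigm
of rodent barrel cortex: every neuron has a principal whisker (PW) it
responds to strongly and early, and neighbouring whiskers (NWs) it responds
to weakly and ~5 ms later. The package is for systems neuroscientists who
want to ask, from spike times and stimulus event times alone: how much
stimulus identity do single cells and ensembles encode, is that information
redundant or synergistic across cells, and how much of it can a downstream
linear decoder actually read out?

## What it computes

**Direct information.** Mutual information between stimulus and response,

    I(S;R) = H(R) - H(R|S)
           = sum_s P(s) sum_r P(r|s) log2 [ P(r|s) / P(r) ],

with `P(s) = N_tr(s)/N_tr_tot` from trial counts. Responses are spike
counts in a post-stimulus window (default 50 ms) or binary spike patterns
(default 5 ms bins, so 2^10 = 1024 possible words per neuron). Plug-in
estimates are corrected for limited-sampling bias by quadratic
extrapolation — refitting `I(x) = a + bx + cx^2` through estimates on the
full data, halves and quarters (x = inverse data fraction) and keeping the
intercept — or by a leave-one-trial-out jackknife.

**Information breakdown.** Ensemble information decomposes exactly as

    I = I_lin + I_sig-sim + I_cor-ind + I_cor-dep,

where `I_lin` sums single-cell informations, `I_sig-sim <= 0` is the cost
of correlated mean tuning, and the last two terms capture
stimulus-independent and stimulus-dependent noise correlations, all built
from the conditionally independent surrogate `nu(r|s) = prod_c P(r_c|s)`.
Negative synergy (`I - I_lin < 0`) is redundancy.

**Decoding.** Stratified four-way cross-validated linear discriminant
analysis on the first ten principal components of the response array,
confusion matrices and their transmitted information (a lower bound on the
direct information), trial-shuffled surrogates (within-class permutation
per neuron: marginals preserved exactly, noise correlations destroyed),
ensemble-variability diagnostics, and ensemble-size curves under
ascending/descending informativeness orderings with comparable-group
matching between INH and best-EXC ensembles.

**Statistics.** Normality-gated two-sample tests (D'Agostino-Pearson gate,
t-test only for normal samples with n >= 20, otherwise Mann-Whitney /
signed-rank), permutation-based two-way ANOVA, and Benjamini-Hochberg FDR
correction.

**Synthetic sessions.** `generate_session()` draws full recording sessions
— blocks of 200 low-frequency trials and 100 trials per periodic frequency
(1–10 Hz), Poisson evoked counts with PW/NW tuning and latency offsets,
adaptation at >= 4 Hz, optional shared-gain noise correlations, spontaneous
firing, and two-cluster spike waveforms — with ground truth for recovery
tests. No external data are needed anywhere.

## Worked example

```r
library(spikeinfo)
library(dplyr)

cfg <- synth_config(n_neurons = 24, seed = 42)
out <- generate_session(cfg)
out$session
#> <recording_session 'synth-42'>
#>   24 neurons (3 INH, 21 EXC), 12 blocks, 7639 s

low <- out$session$blocks$block_id[out$session$blocks$frequency_class == "<1"]
tensor <- build_responses(out$session, low)   # 50 ms window, 5 ms bins
tensor
#> <response_tensor> 400 trials x 24 neurons, 50 ms window / 5 ms bins (10 bins)

# single-cell PW-vs-NW information, QE-corrected, pattern words
info <- single_cell_info(out$session, tensor, seed = 1)
info |> group_by(cell_type) |> summarise(n = n(), mean_bits = mean(info_bits))
#>   cell_type     n mean_bits
#> 1 EXC          21     0.117
#> 2 INH           3     0.255

# ensemble information breakdown on spike counts (5 most informative cells)
labels <- trial_labels(tensor, "location")
breakdown(word_matrix(tensor, tensor$neuron_ids[1:5]), labels)
#> <breakdown_terms (plugin)>
#>   total 0.2477 = lin 0.0642 + sig-sim -0.0016 + cor-ind -0.0059 + cor-dep 0.1910 bits

# population decoding of the deflected whisker
lda_crossval(tensor_features(tensor, space = "pattern"), labels,
             seed = 1, n_components = 10)
#> <decoding_result> 93.0% correct (chance 50.0%), 0.6418 transmitted bits
```

Interpretation: the three inhibitory cells carry about twice the
single-cell location information of the excitatory average (0.255 vs
0.117 bits of a 1-bit maximum for the binary PW-vs-NW comparison); the
five-cell count-based ensemble carries 0.25 bits about which whisker was
deflected; and the full 24-cell population supports 93% correct
single-trial decoding of the deflected whisker against a 50% chance level,
transmitting 0.64 bits through the confusion matrix.

`run_full_analysis(cfg)` chains all stages — per-layer information tables,
ensemble curves in both orderings, INH vs best-EXC redundancy comparison,
noise correlations, trial-shuffling analysis and group statistics — into
one deterministic report; `tidy()`, `glance()` and `autoplot()` methods
cover every result type.

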