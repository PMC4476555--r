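# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# minimal hand-built session: two neurons, two whiskers, deterministic evoked
# spikes (neuron 1 fires 5 ms after C1 onsets, neuron 2 after D1 onsets)
toy_session <- function(n_trials = 4, iti = 2) {
  on_c1 <- seq(10, by = iti, length.out = n_trials)
  on_d1 <- seq(10 + iti * n_trials + 10, by = iti, length.out = n_trials)
  neurons <- tibble::tibble(
    neuron_id = 1:2,
    layer = c("L4", "L5A"),
    column = c("C1", "D1"),
    cell_type = c("INH", "EXC"),
    trough_to_peak_ms = c(0.2, 0.41),
    asymmetry = c(-0.1, -0.34),
    spike_times = list(sort(on_c1 + 0.006), sort(on_d1 + 0.006))
  )
  blocks <- tibble::tibble(
    block_id = 1:2,
    stimulus_id = c("C1", "D1"),
    frequency_class = "<1",
    onset_s = list(on_c1, on_d1)
  )
  recording_session(neurons, blocks,
                    principal_whisker_map = c(`1` = "C1", `2` = "D1"),
                    session_id = "toy")
}

# session in which `n_dup` neurons share identical spike trains tuned to C1
duplicate_neuron_session <- function(n_trials = 50, n_dup = 2) {
  on_c1 <- seq(10, by = 1.5, length.out = n_trials)
  on_d1 <- seq(10 + 1.5 * n_trials + 10, by = 1.5, length.out = n_trials)
  # respond to C1 on 3/4 of trials, to D1 on 1/4 (word distribution with
  # known plug-in information)
  resp_c1 <- on_c1[seq_len(n_trials) %% 4 != 0]
  resp_d1 <- on_d1[seq_len(n_trials) %% 4 == 0]
  st <- sort(c(resp_c1, resp_d1) + 0.005)
  neurons <- tibble::tibble(
    neuron_id = seq_len(n_dup),
    layer = "L4",
    column = "C1",
    cell_type = "EXC",
    trough_to_peak_ms = 0.41,
    asymmetry = -0.34,
    spike_times = rep(list(st), n_dup)
  )
  blocks <- tibble::tibble(
    block_id = 1:2,
    stimulus_id = c("C1", "D1"),
    frequency_class = "<1",
    onset_s = list(on_c1, on_d1)
  )
  recording_session(neurons, blocks,
                    principal_whisker_map = stats::setNames(
                      rep("C1", n_dup), as.character(seq_len(n_dup))),
                    session_id = "dup")
}

# response words for two classes where class A emits `1` with prob pa and
# class B with prob pb (binary alphabet)
binary_words <- function(n_per_class, pa, pb, seed) {
  withr_seed <- function(s, expr) spikeinfo:::with_seed(s, expr)
  withr_seed(seed, {
    list(
      responses = c(stats::rbinom(n_per_class, 1, pa),
                    stats::rbinom(n_per_class, 1, pb)),
      labels = rep(c("A", "B"), each = n_per_class)
    )
  })
}

# independent brute-force mutual information oracle: explicit double sum over
# the joint table (kept deliberately separate from the package's estimator)
brute_force_mi <- function(responses, labels) {
  r_vals <- unique(responses)
  s_vals <- unique(labels)
  n <- length(responses)
  total <- 0
  for (s in s_vals) {
    ps <- sum(labels == s) / n
    for (r in r_vals) {
      prs <- sum(responses == r & labels == s) / sum(labels == s)
      pr <- sum(responses == r) / n
      if (prs > 0) total <- total + ps * prs * log2(prs / pr)
    }
  }
  total
}

# small fast synthetic config for tests that loop over seeds; dots override
fast_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_neurons = 10, trials_low = 80, trials_high = 60,
         frequencies = "<1", seed = seed),
    list(...))
  do.call(synth_config, args)
}
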