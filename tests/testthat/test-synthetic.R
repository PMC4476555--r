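test_that("generation is deterministic and extensible in the seed", {
  cfg <- fast_config(seed = 11)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$session$neurons$spike_times, b$session$neurons$spike_times)
  expect_identical(a$session$blocks$onset_s, b$session$blocks$onset_s)
  expect_identical(a$ground_truth, b$ground_truth)

  # adding neurons must not perturb the existing ones' spike trains
  cfg_big <- fast_config(seed = 11, n_neurons = 12)
  big <- generate_session(cfg_big)
  expect_identical(big$session$neurons$spike_times[1:10],
                   a$session$neurons$spike_times)
})

test_that("silent configurations generate no spikes", {
  cfg <- fast_config(seed = 1, pw_mean_count = c(INH = 0, EXC = 0),
                     spont_rate_hz = c(INH = 0, EXC = 0))
  out <- generate_session(cfg)
  expect_equal(sum(lengths(out$session$neurons$spike_times)), 0)
})

test_that("invalid configurations fail before any generation", {
  expect_error(synth_config(inh_fraction = 1.5), "inh_fraction")
  expect_error(synth_config(frequencies = character(0)), "non-empty")
  expect_error(synth_config(whiskers = "C1"), "whiskers")
  expect_error(synth_config(layer_mix = c("L4" = 0.5, "L5A" = 0.2)), "sum to 1")
})

test_that("evoked counts match the configured Poisson means", {
  cfg <- synth_config(n_neurons = 6, trials_low = 200, frequencies = "<1",
                      pw_mean_count = c(INH = 0.5, EXC = 0.5),
                      layer_gain = c("L2/3" = 1, "L4" = 1, "L5A" = 1,
                                     "L5B/6" = 1),
                      nw_count_ratio = 0.5,
                      spont_rate_hz = c(INH = 0, EXC = 0),
                      informative_exc_fraction = 1,
                      informative_exc_gain = 1, seed = 7)
  out <- generate_session(cfg)
  tensor <- build_responses(out$session)
  gt <- out$ground_truth
  for (i in seq_len(nrow(gt))) {
    pw_trials <- tensor$trial_info$stimulus_id == gt$true_pw[i]
    m <- mean(tensor$counts[pw_trials, i])
    se <- sqrt(0.5 / sum(pw_trials))
    expect_lt(abs(m - 0.5), 3 * se)
  }
})

test_that("protocol summary reflects the block structure and exclusions", {
  cfg <- synth_config(n_neurons = 4, seed = 2)
  out <- generate_session(cfg)
  ps <- protocol_summary(out$session)
  expect_equal(nrow(ps), 12)  # 2 whiskers x 6 frequencies
  expect_true(all(ps$n_trials[ps$frequency_class == "<1"] == 200))
  expect_true(all(ps$n_trials[ps$frequency_class != "<1"] == 100))

  ps_ex <- protocol_summary(out$session, exclude_adapted = TRUE)
  expect_true(all(ps_ex$n_trials[ps_ex$frequency_class %in% c("4", "7", "10")] == 80))
  expect_true(all(ps_ex$n_trials[ps_ex$frequency_class %in% c("<1", "1", "2")] ==
                    ps$n_trials[ps$frequency_class %in% c("<1", "1", "2")]))

  empty <- out$session
  empty$blocks <- empty$blocks[0, ]
  expect_equal(nrow(protocol_summary(empty)), 0)
})

test_that("shared gain raises pairwise noise correlations monotonically", {
  mean_r <- vapply(c(0, 0.4, 0.8), function(g) {
    rs <- vapply(1:3, function(s) {
      cfg <- synth_config(n_neurons = 8, trials_low = 150, frequencies = "<1",
                          shared_gain_sd = g, spont_rate_hz = c(INH = 0, EXC = 0),
                          informative_exc_fraction = 1, seed = 100 + s)
      out <- generate_session(cfg)
      tensor <- build_responses(out$session)
      pairwise_noise_correlation(tensor$counts,
                                 trial_labels(tensor, "location"))$mean_r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_lt(abs(mean_r[1]), 3 / sqrt(300))
  expect_lt(mean_r[1], mean_r[2])
  expect_lt(mean_r[2], mean_r[3])
})

test_that("the analysis pipeline recovers the generator's ground truth", {
  cfg <- synth_config(n_neurons = 8, trials_low = 150, frequencies = "<1",
                      spont_rate_hz = c(INH = 0.5, EXC = 0.2), seed = 21)
  out <- generate_session(cfg)
  sess <- out$session
  gt <- out$ground_truth
  tensor <- build_responses(sess)
  summ <- summarize_responses(sess, tensor)

  # waveform clusters are separated by > 4 SD, so classification is exact
  expect_equal(
    classify_neuron(sess$neurons$trough_to_peak_ms, sess$neurons$asymmetry),
    gt$cell_type)

  for (i in seq_len(nrow(gt))) {
    row <- summ[summ$neuron_id == i & summ$stimulus_id == gt$true_pw[i], ]
    n_tr <- row$n_trials
    expect_lt(abs(row$mean_count - gt$pw_mean_count[i]),
              3 * sqrt(gt$pw_mean_count[i] / n_tr) + 0.05)
    expect_lt(abs(row$median_latency_ms - gt$pw_latency_ms[i]),
              gt$jitter_sd_ms[i])
  }
})

test_that("PW and NW latencies differ by the configured offset", {
  cfg <- synth_config(n_neurons = 6, trials_low = 150, frequencies = "<1",
                      spont_rate_hz = c(INH = 0, EXC = 0),
                      informative_exc_fraction = 1, seed = 33)
  out <- generate_session(cfg)
  tensor <- build_responses(out$session)
  summ <- summarize_responses(out$session, tensor)
  gt <- out$ground_truth
  for (i in seq_len(nrow(gt))) {
    pw_lat <- summ$median_latency_ms[summ$neuron_id == i &
                                       summ$stimulus_id == gt$true_pw[i]]
    nw_lat <- summ$median_latency_ms[summ$neuron_id == i &
                                       summ$stimulus_id != gt$true_pw[i]]
    offset <- nw_lat - pw_lat
    expect_lt(abs(offset - 5), gt$jitter_sd_ms[i])
  }
})
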