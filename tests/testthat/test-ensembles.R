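test_that("neuron ranking is total, tie-broken by id, and reversible", {
  tbl <- tibble::tibble(neuron_id = c(3L, 1L, 2L), info_bits = c(0.2, 0.2, 0.5))
  expect_equal(rank_neurons(tbl, "descending"), c(2L, 1L, 3L))
  expect_equal(rank_neurons(tbl, "ascending"), c(1L, 3L, 2L))
  # all-equal information falls back to id order
  flat <- tibble::tibble(neuron_id = c(9L, 4L, 7L), info_bits = 0.1)
  expect_equal(rank_neurons(flat, "descending"), c(4L, 7L, 9L))
  # distinct values: ascending is the exact reverse of descending
  dis <- tibble::tibble(neuron_id = 1:5, info_bits = c(.5, .1, .4, .2, .3))
  expect_equal(rank_neurons(dis, "ascending"), rev(rank_neurons(dis, "descending")))
})

test_that("ranking recovers the generator's informative neurons", {
  hits <- vapply(1:20, function(s) {
    cfg <- fast_config(seed = 600 + s, n_neurons = 10, trials_low = 120,
                       nw_count_ratio = 0.3)
    out <- generate_session(cfg)
    tensor <- build_responses(out$session)
    info <- single_cell_info(out$session, tensor, space = "count",
                             method = "plugin")
    truth <- out$ground_truth$neuron_id[out$ground_truth$informative]
    top <- utils::head(rank_neurons(info, "descending"), length(truth))
    mean(truth %in% top)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ensemble curves honour exact redundancy identities", {
  s <- duplicate_neuron_session(n_trials = 48, n_dup = 3)
  tensor <- build_responses(s)
  labels <- trial_labels(tensor, "location")
  curve <- ensemble_curve(tensor, 1:3, "ensemble_mi", space = "count",
                          labels = labels)
  i1 <- plugin_mi(response_words(tensor, 1, "count"), labels)$value
  # size 1: ensemble equals the single cell, redundancy exactly 0
  expect_equal(curve$value[1], i1, tolerance = 1e-12)
  expect_equal(curve$redundancy[1], 0, tolerance = 1e-12)
  # duplicated neurons: value flat, redundancy -I at size 2, -2I at size 3
  expect_equal(curve$value[2], i1, tolerance = 1e-12)
  expect_equal(curve$redundancy[2], -i1, tolerance = 1e-12)
  expect_equal(curve$redundancy[3], -2 * i1, tolerance = 1e-12)
  # adding a duplicate never increases ensemble information
  expect_lte(curve$value[3], curve$value[1] + 0.02)
})

test_that("curve values stay below the stimulus entropy and orders meet at the top", {
  cfg <- fast_config(seed = 9, n_neurons = 6, trials_low = 100)
  out <- generate_session(cfg)
  tensor <- build_responses(out$session)
  labels <- trial_labels(tensor, "location")
  hs <- -sum(prop.table(table(labels)) * log2(prop.table(table(labels))))
  info <- single_cell_info(out$session, tensor, space = "count",
                           method = "plugin")
  desc <- ensemble_curve(tensor, rank_neurons(info, "descending"),
                         space = "count", labels = labels)
  asc <- ensemble_curve(tensor, rank_neurons(info, "ascending"),
                        space = "count", labels = labels)
  expect_true(all(desc$value <= hs + 1e-9))
  # same final ensemble, same value
  expect_equal(desc$value[nrow(desc)], asc$value[nrow(asc)], tolerance = 1e-12)
})

test_that("pattern-based ensemble information refuses oversized groups", {
  cfg <- fast_config(seed = 10, n_neurons = 12)
  out <- generate_session(cfg)
  tensor <- build_responses(out$session)
  expect_error(
    ensemble_curve(tensor, tensor$neuron_ids, space = "pattern",
                   max_pattern_neurons = 10),
    "capped")
})

test_that("comparable-group matching finds the smallest equally informative prefix", {
  mk_curve <- function(ids, values) {
    out <- tibble::tibble(size = seq_along(ids), neuron_id = ids,
                          value = values, redundancy = NA_real_)
    structure(out, class = c("ensemble_curve", class(out)),
              measure = "ensemble_mi", space = "count", estimator = "plugin",
              order_mode = "descending", ordering = ids)
  }
  inh <- mk_curve(1:8, seq(0.3, 0.87, length.out = 8))
  exc <- mk_curve(11:25, c(seq(0.2, 0.85, length.out = 8),
                           0.87, seq(0.88, 0.95, length.out = 6)))
  gm <- match_comparable_groups(inh, exc)
  expect_length(gm$exc_ids, 9)
  expect_true(gm$matched)
  expect_gte(gm$exc_info, gm$inh_info)

  # uniformly more informative EXC: smaller matched group
  exc_hot <- mk_curve(11:18, seq(0.5, 1.0, length.out = 8))
  gm2 <- match_comparable_groups(inh, exc_hot)
  expect_lt(length(gm2$exc_ids), length(gm$inh_ids))

  # no prefix reaches the INH level: full prefix, flagged unmatched
  exc_weak <- mk_curve(11:14, seq(0.1, 0.4, length.out = 4))
  gm3 <- match_comparable_groups(inh, exc_weak)
  expect_length(gm3$exc_ids, 4)
  expect_false(gm3$matched)
})

test_that("the per-session redundancy report assembles all components", {
  cfg <- fast_config(seed = 13, n_neurons = 12, trials_low = 100, inh_fraction = 0.25)
  out <- generate_session(cfg)
  tensor <- build_responses(out$session)
  rep_row <- redundancy_comparison(out$session, tensor, seed = 2)
  expect_equal(nrow(rep_row), 1)
  expect_true(all(c("inh_redundancy", "exc_redundancy", "inh_sig_sim",
                    "exc_sig_sim", "inh_noise_r", "exc_noise_r",
                    "matched") %in% names(rep_row)))
  expect_lte(rep_row$inh_sig_sim, 1e-9)
  expect_lte(rep_row$exc_sig_sim, 1e-9)

  # single-type sessions are a user error
  mono <- out$session
  mono$neurons$cell_type <- "EXC"
  expect_error(redundancy_comparison(mono, tensor), "each cell type")
})
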