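test_that("PCA reduction orders components and preserves cluster geometry", {
  # rank-1 data: one component carries all variance
  set.seed(1)
  u <- rnorm(50)
  x <- cbind(u, 2 * u, -u)
  p <- reduce_dimensions(x, 2)
  expect_gt(p$sdev[1]^2 / sum(p$sdev^2), 0.999)

  # two clusters separated along a coordinate axis: separation preserved
  x2 <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
              matrix(rnorm(200, 5, 0.1), 100, 2))
  p2 <- reduce_dimensions(x2, 2)
  d_orig <- sqrt(sum((colMeans(x2[1:100, ]) - colMeans(x2[101:200, ]))^2))
  d_red <- sqrt(sum((colMeans(p2$scores[1:100, ]) -
                       colMeans(p2$scores[101:200, ]))^2))
  expect_gte(d_red / d_orig, 0.99)

  # a 44-neuron x 10-bin array reduces to exactly 10 columns
  x3 <- matrix(rbinom(200 * 440, 1, 0.1), 200, 440)
  p3 <- reduce_dimensions(x3, 10)
  expect_equal(ncol(p3$scores), 10)

  # asking for more components than exist warns and uses all
  expect_warning(reduce_dimensions(matrix(rnorm(20), 10, 2), 5), "available")

  # deterministic sign convention: projection of new data matches scores
  expect_equal(project_pca(p2, x2), p2$scores)
})

test_that("cross-validated LDA separates separable data and books folds correctly", {
  set.seed(2)
  x <- rbind(matrix(rnorm(200, 0, 0.2), 100, 2),
             matrix(rnorm(200, 4, 0.2), 100, 2))
  y <- rep(c("A", "B"), each = 100)
  res <- lda_crossval(x, y, seed = 1)
  expect_equal(res$performance, 100)
  # four-way CV: exactly 75% of trials train every fold
  expect_equal(res$n_train_per_fold / (res$n_train_per_fold + res$n_test_per_fold),
               rep(0.75, 4))
  # confusion rows sum to the per-class trial counts
  expect_equal(unname(rowSums(res$confusion)), c(100, 100))
  expect_equal(res$performance,
               100 * sum(diag(res$confusion)) / sum(res$confusion))
  expect_error(lda_crossval(x[1:6, ], rep(c("A", "B"), 3), n_folds = 4),
               ">= 4 trials")
})

test_that("a single mislabeled extreme point is the only test error", {
  x <- matrix(c(seq(-2.5, -1.8, length.out = 20),
                seq(1.8, 2.5, length.out = 20), 2.6), ncol = 1)
  y <- c(rep("A", 20), rep("B", 20), "A")
  res <- lda_crossval(x, y, n_folds = 4, seed = 7)
  expect_equal(sum(res$confusion) - sum(diag(res$confusion)), 1)
  expect_equal(unname(res$confusion["A", "B"]), 1)
})

test_that("label-independent features decode at chance", {
  perf <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rbinom(200 * 40, 1, 0.2), 200, 40)
    y <- rep(c("A", "B"), each = 100)
    lda_crossval(x, y, seed = s, n_components = 10)$performance
  }, numeric(1))
  expect_lt(abs(mean(perf) - 50), 8)
})

test_that("the decoder agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  x <- rbind(matrix(rnorm(300, 0, 1), 150, 2),
             matrix(rnorm(300, 1.5, 1), 150, 2))
  y <- factor(rep(c("A", "B"), each = 150))
  ours <- spikeinfo:::fit_lda(x, y, shrinkage = 0)
  pred_ours <- spikeinfo:::predict_lda(ours, x)
  ref <- MASS::lda(x, y)
  pred_ref <- as.character(predict(ref, x)$class)
  expect_gt(mean(pred_ours == pred_ref), 0.99)
})

test_that("trial shuffling preserves marginals and destroys co-fluctuations", {
  cfg <- fast_config(seed = 44, shared_gain_sd = 0.8, trials_low = 100,
                     informative_exc_fraction = 1)
  out <- generate_session(cfg)
  tensor <- build_responses(out$session)
  labels <- tensor$trial_info$stimulus_id
  sh <- shuffle_trials(tensor, seed = 5)

  # per-class per-neuron count multisets identical
  for (cl in unique(labels)) {
    tr <- labels == cl
    for (j in seq_along(tensor$neuron_ids)) {
      expect_equal(sort(sh$counts[tr, j]), sort(tensor$counts[tr, j]))
    }
  }
  # per-class mean counts exactly preserved (signal correlations kept)
  for (cl in unique(labels)) {
    tr <- labels == cl
    expect_equal(colMeans(sh$counts[tr, ]), colMeans(tensor$counts[tr, ]))
  }
  # pairwise noise correlations collapse
  r_before <- pairwise_noise_correlation(tensor$counts, labels)$mean_r
  r_after <- pairwise_noise_correlation(sh$counts, labels)$mean_r
  expect_gt(r_before, 0.2)
  expect_lt(abs(r_after), 0.1)
})

test_that("ensemble variability matches hand-computed values and shrinks on shuffling", {
  # two-neuron, two-trial toy: trial means 0.5 and 1.5 -> sample SD 0.7071
  expect_equal(ensemble_variability(rbind(c(1, 0), c(1, 2))),
               0.7071068, tolerance = 1e-6)
  expect_equal(ensemble_variability(rbind(c(2, 3), c(2, 3), c(2, 3))), 0)

  decreases <- vapply(1:5, function(s) {
    cfg <- fast_config(seed = 400 + s, shared_gain_sd = 0.5,
                       informative_exc_fraction = 1)
    out <- generate_session(cfg)
    tensor <- build_responses(out$session)
    sh <- shuffle_trials(tensor, seed = s)
    ensemble_variability(tensor) - ensemble_variability(sh)
  }, numeric(1))
  expect_true(all(decreases > 0))
})

test_that("shuffle-gain analysis wires gains to variability decreases", {
  pts <- tibble::tibble(
    performance = c(60, 70, 80, 65, 75),
    performance_shuffled = c(60.5, 74, 88, 66, 80),
    sd_count = c(0.07, 0.08, 0.09, 0.075, 0.085),
    sd_count_shuffled = c(0.069, 0.06, 0.05, 0.072, 0.06))
  res <- shuffle_gain_analysis(pts, seed = 1)
  expect_gt(res$r, 0.9)
  expect_lt(res$p_value, 0.05)
  expect_equal(nrow(res$table), 5)
  expect_error(shuffle_gain_analysis(pts[1:2, ]), ">= 3 points")

  # neutral shuffles: no spread in the gains -> correlation undefined
  flat <- tibble::tibble(performance = c(70, 70, 70),
                         performance_shuffled = c(70, 70, 70),
                         sd_count = c(0.07, 0.07, 0.07),
                         sd_count_shuffled = c(0.07, 0.07, 0.07))
  res_flat <- shuffle_gain_analysis(flat, seed = 1)
  expect_true(is.na(res_flat$r))
})

test_that("conditionally independent data gains nothing from shuffling", {
  deltas <- vapply(1:20, function(s) {
    cfg <- fast_config(seed = 500 + s, shared_gain_sd = 0,
                       informative_exc_fraction = 1)
    out <- generate_session(cfg)
    tensor <- build_responses(out$session)
    labels <- trial_labels(tensor, "location")
    sh <- shuffle_trials(tensor, seed = s)
    a <- lda_crossval(tensor_features(tensor, space = "count"), labels,
                      seed = s, n_components = 10)$performance
    b <- lda_crossval(tensor_features(sh, space = "count"), labels,
                      seed = s, n_components = 10)$performance
    b - a
  }, numeric(1))
  # paired test: shuffled vs original indistinguishable
  p <- suppressWarnings(stats::wilcox.test(deltas)$p.value)
  expect_gt(p, 0.05)
})
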