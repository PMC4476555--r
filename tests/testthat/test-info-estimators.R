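test_that("plug-in information matches closed forms and the brute-force oracle", {
  # constant responses carry nothing
  expect_equal(plugin_mi(rep(3, 20), rep(c("A", "B"), 10))$value, 0)
  # perfectly class-specific balanced responses reach the 1-bit ceiling
  expect_equal(plugin_mi(rep(c(0, 1), each = 50),
                         rep(c("A", "B"), each = 50))$value, 1)
  # H(R) = 1, H(R|S) = h(0.75): I = 1 - 0.8113 = 0.1887 bits
  r <- c(1, 1, 1, 0, 1, 0, 0, 0)
  l <- rep(c("A", "B"), each = 4)
  expect_equal(plugin_mi(r, l)$value, brute_force_mi(r, l))
  expect_equal(plugin_mi(r, l)$value, 0.18872187554, tolerance = 1e-9)
  est <- plugin_mi(r, l)
  expect_equal(est$value, est$h_response - est$h_noise)

  # P(s) comes from trial counts, not assumed uniform
  r2 <- c(rep(1, 30), rep(0, 10))
  l2 <- c(rep("A", 30), rep("B", 10))
  expect_equal(plugin_mi(r2, l2)$value, brute_force_mi(r2, l2))

  expect_error(plugin_mi(1:5, rep("A", 5)), "two stimulus classes")
  expect_error(plugin_mi(numeric(0), character(0)), "empty")
})

test_that("plug-in estimates agree with brute force on random small alphabets", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:60, 1)
    r <- sample(0:3, n, replace = TRUE)
    l <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    if (length(unique(l)) < 2) next
    expect_equal(plugin_mi(r, l)$value, brute_force_mi(r, l),
                 tolerance = 1e-12)
    # bounds: 0 <= I <= min(H(S), log2 |alphabet|)
    hs <- -sum(prop.table(table(l)) * log2(prop.table(table(l))))
    v <- plugin_mi(r, l)$value
    expect_gte(v, 0)
    expect_lte(v, min(hs, log2(length(unique(r)))) + 1e-12)
  }
})

test_that("plug-in information is invariant to trial order and word relabeling", {
  set.seed(42)
  r <- sample(0:5, 80, replace = TRUE)
  l <- rep(c("A", "B"), 40)
  v <- plugin_mi(r, l)$value
  perm <- sample(80)
  expect_equal(plugin_mi(r[perm], l[perm])$value, v)
  expect_equal(plugin_mi(letters[r + 1], l)$value, v)
})

test_that("quadratic extrapolation recovers exact synthetic bias laws", {
  # exact quadratic: I(x) = a + b x + c x^2 at x = 1, 2, 4
  a <- 0.42; b <- 0.31; c <- -0.05
  y <- a + b * c(1, 2, 4) + c * c(1, 2, 4)^2
  expect_equal(qe_extrapolate(y[1], y[2], y[3]), a, tolerance = 1e-12)
  # exact linear law a + b/N is the c = 0 special case
  y2 <- a + b * c(1, 2, 4)
  expect_equal(qe_extrapolate(y2[1], y2[2], y2[3]), a, tolerance = 1e-12)
})

test_that("QE is a fixed point on zero-bias data and removes bias on null data", {
  # perfectly class-specific responses: every partition gives 1 bit
  r <- rep(c(0, 1), each = 64)
  l <- rep(c("A", "B"), each = 64)
  est <- qe_corrected_mi(r, l, seed = 1)
  expect_equal(est$value, plugin_mi(r, l)$value, tolerance = 1e-12)

  # independent labels: plug-in is biased up, QE centres near zero
  qe_vals <- numeric(50)
  plugin_vals <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    r <- sample(0:15, 200, replace = TRUE)
    l <- rep(c("A", "B"), each = 100)
    qe_vals[s] <- qe_corrected_mi(r, l, seed = s)$value
    plugin_vals[s] <- plugin_mi(r, l)$value
  }
  expect_lt(abs(mean(qe_vals)), 0.02)
  expect_lt(mean(abs(qe_vals)), mean(plugin_vals))
  expect_gt(mean(plugin_vals), 0.03)  # the bias QE is removing is real

  expect_error(qe_corrected_mi(rep(0:1, 4), rep(c("A", "B"), each = 4)),
               ">= 8 trials")
})

test_that("jackknife correction shrinks the null bias and keeps fixed points", {
  # perfectly class-specific balanced data sits at the 1-bit ceiling up to
  # the O(1/N) prior perturbation that leaving one trial out induces
  r <- rep(c(0, 1), each = 50)
  l <- rep(c("A", "B"), each = 50)
  expect_equal(jackknife_mi(r, l)$value, 1, tolerance = 0.01)
  expect_equal(jackknife_mi(rep(1, 20), rep(c("A", "B"), 10))$value, 0)

  jk_vals <- numeric(50)
  plugin_vals <- numeric(50)
  for (s in 1:50) {
    set.seed(s + 100)
    r <- sample(0:7, 100, replace = TRUE)
    l <- rep(c("A", "B"), each = 50)
    jk_vals[s] <- jackknife_mi(r, l)$value
    plugin_vals[s] <- plugin_mi(r, l)$value
  }
  expect_lt(mean(abs(jk_vals)), mean(plugin_vals))
})

test_that("the information-versus-trials curve exposes and removes bias", {
  set.seed(9)
  r <- sample(0:15, 400, replace = TRUE)
  l <- rep(c("A", "B"), each = 200)
  curve <- info_vs_trials(r, l, fractions = c(0.25, 0.5, 1),
                          method = "plugin", n_repeats = 10, seed = 2)
  # fraction 1 equals the full-data estimator
  expect_equal(curve$mean_bits[curve$fraction == 1], plugin_mi(r, l)$value)
  # plug-in bias shrinks as trials grow: decreasing in n_trials
  expect_gt(curve$mean_bits[curve$fraction == 0.25],
            curve$mean_bits[curve$fraction == 1])

  # strongly tuned data: QE curve flat within 0.05 bits for n >= 100
  wl <- binary_words(400, 0.9, 0.1, seed = 3)
  qc <- info_vs_trials(wl$responses, wl$labels, fractions = c(0.25, 0.5, 1),
                       method = "qe", n_repeats = 8, seed = 4)
  expect_lt(max(qc$mean_bits) - min(qc$mean_bits), 0.05)
})

test_that("transmitted information follows the confusion-matrix closed forms", {
  expect_equal(transmitted_info(diag(c(50, 50))), 1)
  expect_equal(transmitted_info(matrix(25, 2, 2)), 0)
  expect_equal(transmitted_info(rbind(c(75, 25), c(25, 75))),
               0.18872187554, tolerance = 1e-9)
  expect_error(transmitted_info(matrix(0, 2, 2)), "positive")
  expect_error(transmitted_info(rbind(c(-1, 2), c(3, 4))), "non-negative")
})
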