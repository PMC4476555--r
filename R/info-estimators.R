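# Discrete stimulus information from trial-wise response words.
#
# Responses are opaque discrete symbols (a spike count, a packed spike
# pattern, or a serialised ensemble word); probabilities are empirical
# frequencies with P(s) taken from the trial counts, never assumed uniform.

joint_counts <- function(responses, labels) {
  if (length(responses) == 0) stop_spikeinfo("empty response vector")
  if (length(responses) != length(labels)) {
    stop_spikeinfo("responses and labels differ in length")
  }
  keep <- !is.na(labels)
  responses <- responses[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop_spikeinfo("need at least two stimulus classes")
  }
  table(response = factor(responses), stimulus = factor(labels))
}

mi_from_counts <- function(M) {
  N <- sum(M)
  h_response <- entropy_bits(rowSums(M) / N)
  ps <- colSums(M) / N
  h_noise <- 0
  for (s in which(ps > 0)) {
    h_noise <- h_noise + ps[s] * entropy_bits(M[, s] / sum(M[, s]))
  }
  h_noise <- unname(h_noise)
  list(value = h_response - h_noise, h_response = h_response,
       h_noise = h_noise, n = N)
}

new_info_estimate <- function(value, method, n_trials_used, response_space,
                              h_response = NA_real_, h_noise = NA_real_,
                              diagnostics = NULL) {
  structure(
    list(value = value, method = method, n_trials_used = n_trials_used,
         response_space = response_space, h_response = h_response,
         h_noise = h_noise, diagnostics = diagnostics),
    class = "info_estimate"
  )
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("<info_estimate> %.4f bits (%s, %d trials, %s space)\n",
              x$value, x$method, x$n_trials_used, x$response_space))
  invisible(x)
}

#' Plug-in mutual information between stimulus and response
#'
#' Empirical-frequency estimate of `I(S;R) = H(R) - H(R|S)` in bits, where
#' `H(R)` is the response entropy and `H(R|S)` the noise entropy, with the
#' stimulus probabilities `P(s)` taken from the per-class trial counts.
#' The plug-in estimate is biased upward when the response alphabet is not
#' well sampled; see [qe_corrected_mi()] and [jackknife_mi()].
#'
#' @param responses Vector of discrete response words, one per trial (any
#'   hashable type: counts, packed patterns, serialised ensemble words).
#' @param labels Stimulus class per trial (`NA` labels are dropped).
#' @param response_space Free-text tag stored in the result.
#' @return An `info_estimate` (value in bits plus diagnostic entropies).
#' @export
#' @examples
#' plugin_mi(c(1, 1, 1, 0, 1, 0, 0, 0), rep(c("A", "B"), each = 4))
plugin_mi <- function(responses, labels, response_space = "word") {
  M <- joint_counts(responses, labels)
  est <- mi_from_counts(M)
  new_info_estimate(est$value, "plugin", est$n, response_space,
                    est$h_response, est$h_noise)
}

#' Quadratic-extrapolation closed form
#'
#' Fits `I(x) = a + b x + c x^2`, with `x` the inverse data fraction, through
#' the estimates at the full data (`x = 1`), halves (`x = 2`) and quarters
#' (`x = 4`), and returns the extrapolation `a` at `x -> 0` (infinite data).
#'
#' @param i_full,i_half,i_quarter Information estimates at the three
#'   fractions (halves/quarters already averaged over their partitions).
#' @return The bias-corrected intercept `a`, in bits.
#' @export
qe_extrapolate <- function(i_full, i_half, i_quarter) {
  x <- c(1, 2, 4)
  V <- cbind(1, x, x^2)
  unname(solve(V, c(i_full, i_half, i_quarter))[1])
}

# stratified disjoint split of trial indices into n_parts parts
stratified_parts <- function(labels, n_parts) {
  parts <- vector("list", n_parts)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    grp <- rep(seq_len(n_parts), length.out = length(idx))
    # rep() assigns cyclically; use contiguous chunks of the shuffled order
    sizes <- tabulate(grp, n_parts)
    splits <- split(idx, rep(seq_len(n_parts), sizes))
    for (p in seq_len(n_parts)) parts[[p]] <- c(parts[[p]], splits[[p]])
  }
  parts
}

#' Bias-corrected mutual information by quadratic extrapolation (QE)
#'
#' The plug-in information is recomputed on class-stratified random disjoint
#' halves and quarters of the trials; the three values (full, mean of halves,
#' mean of quarters) are extrapolated to infinite data with
#' [qe_extrapolate()]. Partitioning is repeated `n_partitions` times and the
#' sub-sampled estimates averaged before the fit. Corrected values may be
#' slightly negative and are reported unclipped unless `clip_at_zero`.
#'
#' @inheritParams plugin_mi
#' @param n_partitions Number of random partition repeats (default 2).
#' @param seed Seed for the partitioning.
#' @param clip_at_zero Clip negative corrected values to 0 (default `FALSE`).
#' @return An `info_estimate`; `diagnostics` holds the three fitted points.
#' @export
qe_corrected_mi <- function(responses, labels, n_partitions = 2, seed = NULL,
                            response_space = "word", clip_at_zero = FALSE) {
  keep <- !is.na(labels)
  responses <- responses[keep]
  labels <- labels[keep]
  tab <- table(labels)
  if (length(tab) < 2) stop_spikeinfo("need at least two stimulus classes")
  if (any(tab < 8)) {
    stop_spikeinfo(paste0(
      "QE needs >= 8 trials per class so that quarters are non-degenerate; ",
      "use plugin_mi() or jackknife_mi() instead"))
  }
  full <- plugin_mi(responses, labels, response_space)
  sub_mean <- function(n_parts, s) {
    vals <- with_seed(s, {
      unlist(lapply(seq_len(n_partitions), function(r) {
        parts <- stratified_parts(labels, n_parts)
        vapply(parts, function(idx) {
          plugin_mi(responses[idx], labels[idx])$value
        }, numeric(1))
      }))
    })
    mean(vals)
  }
  i_half <- sub_mean(2, if (is.null(seed)) NULL else derive_seed(seed, 2))
  i_quarter <- sub_mean(4, if (is.null(seed)) NULL else derive_seed(seed, 4))
  a <- qe_extrapolate(full$value, i_half, i_quarter)
  if (clip_at_zero) a <- max(a, 0)
  new_info_estimate(a, "qe", full$n_trials_used, response_space,
                    full$h_response, full$h_noise,
                    diagnostics = list(i_full = full$value, i_half = i_half,
                                       i_quarter = i_quarter))
}

#' Bias-corrected mutual information by jackknife
#'
#' Leave-one-trial-out correction
#' `I_jk = N I_full - (N - 1) mean(I_(-t))`. Trials sharing the same
#' (response, stimulus) cell give identical leave-one-out estimates, so only
#' one estimate per occupied cell is computed.
#'
#' @inheritParams plugin_mi
#' @return An `info_estimate`.
#' @export
jackknife_mi <- function(responses, labels, response_space = "word") {
  M <- joint_counts(responses, labels)
  if (any(colSums(M) < 2)) {
    stop_spikeinfo("jackknife needs >= 2 trials per class")
  }
  est <- mi_from_counts(M)
  N <- est$n
  loo_sum <- 0
  occ <- which(M > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(occ))) {
    M1 <- M
    M1[occ[k, 1], occ[k, 2]] <- M1[occ[k, 1], occ[k, 2]] - 1
    loo_sum <- loo_sum + M[occ[k, 1], occ[k, 2]] * mi_from_counts(M1)$value
  }
  value <- N * est$value - (N - 1) * (loo_sum / N)
  new_info_estimate(value, "jackknife", N, response_space,
                    est$h_response, est$h_noise)
}

info_estimator <- function(method) {
  switch(method,
    plugin = plugin_mi,
    qe = qe_corrected_mi,
    jackknife = jackknife_mi,
    stop_spikeinfo(sprintf("unknown estimator '%s'", method))
  )
}

#' Information as a function of the number of trials
#'
#' Trial-decay diagnostic: the estimator is applied to stratified random
#' subsamples at each fraction of the data; a flat curve indicates that the
#' trial count suffices for a stable (de-biased) estimate, while a decaying
#' plug-in curve exposes limited-sampling bias.
#'
#' @inheritParams plugin_mi
#' @param fractions Fractions of trials to keep (in (0, 1\]).
#' @param method `"plugin"`, `"qe"` or `"jackknife"`.
#' @param n_repeats Subsample repeats per fraction (fraction 1 is computed
#'   once on the full data).
#' @param seed Seed for subsampling.
#' @return Tibble: `fraction`, `n_trials`, `mean_bits`, `sd_bits`, `method`.
#' @export
info_vs_trials <- function(responses, labels, fractions = c(0.25, 0.5, 1),
                           method = "plugin", n_repeats = 10, seed = NULL) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  keep <- !is.na(labels)
  responses <- responses[keep]
  labels <- labels[keep]
  est_fun <- info_estimator(method)
  est_value <- function(r, l, s) {
    if (method == "qe") est_fun(r, l, seed = s)$value else est_fun(r, l)$value
  }
  rows <- list()
  for (fr in sort(fractions)) {
    if (fr == 1) {
      v <- est_value(responses, labels, derive_seed(seed %||% 0, 1))
      rows[[length(rows) + 1]] <- tibble(fraction = 1,
                                         n_trials = length(labels),
                                         mean_bits = v, sd_bits = 0,
                                         method = method)
      next
    }
    per_class <- table(labels)
    if (any(floor(per_class * fr) < 2)) {
      warn(sprintf("fraction %.3g leaves < 2 trials in some class; skipped", fr))
      next
    }
    vals <- vapply(seq_len(n_repeats), function(rep_i) {
      idx <- with_seed(derive_seed(seed %||% 0, round(1e4 * fr), rep_i), {
        unlist(lapply(unique(labels), function(cl) {
          cl_idx <- which(labels == cl)
          sample(cl_idx, floor(length(cl_idx) * fr))
        }))
      })
      tryCatch(est_value(responses[idx], labels[idx],
                         derive_seed(seed %||% 0, round(1e4 * fr), rep_i, 7)),
               error = function(e) NA_real_)
    }, numeric(1))
    rows[[length(rows) + 1]] <- tibble(
      fraction = fr, n_trials = sum(floor(per_class * fr)),
      mean_bits = mean(vals, na.rm = TRUE),
      sd_bits = sd(vals, na.rm = TRUE), method = method)
  }
  bind_rows(rows)
}

#' Transmitted information of a confusion matrix
#'
#' Mutual information between true and decoded stimulus class, computed from
#' a decoder's confusion matrix (rows = true class, columns = decoded class).
#' It is a lower bound on the direct stimulus information in the responses.
#'
#' @param confusion Square-ish matrix of non-negative counts.
#' @return Information in bits.
#' @export
transmitted_info <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0) {
    stop_spikeinfo("confusion matrix must be non-negative with positive total")
  }
  N <- sum(confusion)
  p <- confusion / N
  pi_ <- rowSums(p)
  pj <- colSums(p)
  tot <- 0
  for (i in which(pi_ > 0)) {
    for (j in which(pj > 0)) {
      if (p[i, j] > 0) {
        tot <- tot + p[i, j] * log2(p[i, j] / (pi_[i] * pj[j]))
      }
    }
  }
  tot
}
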