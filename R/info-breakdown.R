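# Decomposition of ensemble information into linear, signal-similarity and
# noise-correlation components, following the information-breakdown
# methodology for discrete per-neuron response words:
#
#   I(S;R) = I_lin + syn
#          = I_lin + I_sig_sim + I_cor_ind + I_cor_dep
#
# built from the conditionally-independent surrogate
#   nu(r|s) = prod_c P(r_c|s),   nu(r) = sum_s P(s) nu(r|s).

#' Linear term of the information breakdown
#'
#' Sum of the information carried by each neuron individually,
#' `I_lin = sum_c I(R_c; S)` (plug-in).
#'
#' @param words Trials x neurons matrix of discrete per-neuron response words
#'   (see [word_matrix] building via [response_words()]).
#' @param labels Stimulus class per trial.
#' @return Bits.
#' @export
linear_term <- function(words, labels) {
  words <- as.matrix(words)
  sum(vapply(seq_len(ncol(words)), function(c) {
    plugin_mi(words[, c], labels)$value
  }, numeric(1)))
}

#' Information breakdown of an ensemble response
#'
#' Decomposes the ensemble information into the linear term (sum of
#' single-cell informations), the signal-similarity term (effect of
#' correlated mean tuning across neurons; always <= 0), and the
#' stimulus-independent and stimulus-dependent noise-correlation terms. All
#' terms are computed from the same plug-in probabilities so the sum identity
#' `i_total = i_lin + i_sig_sim + i_cor_ind + i_cor_dep` is exact; with
#' `method = "qe"` every term is additionally extrapolated to infinite data
#' (the identity is preserved because the extrapolation is linear).
#'
#' The surrogate distribution `nu` lives on the product of the per-neuron
#' word alphabets, which is enumerated exactly; `state_cap` bounds the
#' enumeration (counts in a 50 ms window keep <= 10-neuron groups far below
#' the cap, spike patterns do not -- use counts for large groups).
#'
#' @inheritParams linear_term
#' @param method `"plugin"` or `"qe"` (term-wise quadratic extrapolation).
#' @param n_partitions,seed Passed to the QE partitioning.
#' @param state_cap Maximum number of product states enumerated.
#' @return A `breakdown_terms` object: `i_total`, `i_lin`, `synergy`,
#'   `i_sig_sim`, `i_cor`, `i_cor_ind`, `i_cor_dep`, `method`; the
#'   `diagnostics` element carries the directly-computed stimulus-dependent
#'   term used for cross-checking.
#' @export
breakdown <- function(words, labels, method = c("plugin", "qe"),
                      n_partitions = 2, seed = NULL, state_cap = 2^23) {
  method <- match.arg(method)
  words <- as.matrix(words)
  if (ncol(words) < 2) stop_spikeinfo("breakdown needs >= 2 neurons")
  keep <- !is.na(labels)
  words <- words[keep, , drop = FALSE]
  labels <- labels[keep]

  if (method == "plugin") {
    return(breakdown_plugin(words, labels, state_cap))
  }

  # term-wise QE: extrapolate every component from full / halves / quarters
  tab <- table(labels)
  if (any(tab < 8)) {
    stop_spikeinfo("QE breakdown needs >= 8 trials per class")
  }
  term_vec <- function(bt) {
    c(bt$i_total, bt$i_lin, bt$i_sig_sim, bt$i_cor_ind, bt$i_cor_dep)
  }
  full <- breakdown_plugin(words, labels, state_cap)
  sub_terms <- function(n_parts, s) {
    acc <- with_seed(s, {
      reps <- lapply(seq_len(n_partitions), function(r) {
        parts <- stratified_parts(labels, n_parts)
        vals <- lapply(parts, function(idx) {
          term_vec(breakdown_plugin(words[idx, , drop = FALSE], labels[idx],
                                    state_cap))
        })
        Reduce(`+`, vals) / length(vals)
      })
      Reduce(`+`, reps) / length(reps)
    })
    acc
  }
  half <- sub_terms(2, if (is.null(seed)) NULL else derive_seed(seed, 2))
  quarter <- sub_terms(4, if (is.null(seed)) NULL else derive_seed(seed, 4))
  fullv <- term_vec(full)
  corr <- vapply(seq_along(fullv), function(k) {
    qe_extrapolate(fullv[k], half[k], quarter[k])
  }, numeric(1))
  new_breakdown(corr[1], corr[2], corr[3], corr[4], corr[5], "qe",
                diagnostics = full$diagnostics)
}

new_breakdown <- function(i_total, i_lin, i_sig_sim, i_cor_ind, i_cor_dep,
                          method, diagnostics = NULL) {
  structure(
    list(i_total = i_total, i_lin = i_lin, synergy = i_total - i_lin,
         i_sig_sim = i_sig_sim, i_cor = i_cor_ind + i_cor_dep,
         i_cor_ind = i_cor_ind, i_cor_dep = i_cor_dep, method = method,
         diagnostics = diagnostics),
    class = "breakdown_terms"
  )
}

#' @export
print.breakdown_terms <- function(x, ...) {
  cat(sprintf(paste0(
    "<breakdown_terms (%s)>\n",
    "  total %.4f = lin %.4f + sig-sim %.4f + cor-ind %.4f + cor-dep %.4f bits\n"),
    x$method, x$i_total, x$i_lin, x$i_sig_sim, x$i_cor_ind, x$i_cor_dep))
  invisible(x)
}

breakdown_plugin <- function(words, labels, state_cap) {
  n_c <- ncol(words)
  n_tr <- nrow(words)
  classes <- sort(unique(labels))
  ps <- as.numeric(table(factor(labels, classes))) / n_tr

  levels_c <- lapply(seq_len(n_c), function(c) sort(unique(words[, c])))
  K <- vapply(levels_c, length, integer(1))
  G <- prod(K)
  if (G > state_cap) {
    stop_spikeinfo(sprintf(
      "product response space has %.3g states (cap %.3g); use spike counts or a smaller group",
      G, state_cap))
  }

  idx <- vapply(seq_len(n_c), function(c) match(words[, c], levels_c[[c]]),
                integer(n_tr))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = n_c)
  stride <- cumprod(c(1, K[-n_c]))
  row_id <- as.integer(1 + (idx - 1) %*% stride)

  # per-class marginals on each neuron's global alphabet
  p_marg <- lapply(seq_along(classes), function(si) {
    tr <- labels == classes[si]
    lapply(seq_len(n_c), function(c) {
      tabulate(idx[tr, c], nbins = K[c]) / sum(tr)
    })
  })

  # nu(.|s) over the product grid in mixed-radix order (neuron 1 fastest):
  # successive outer products of the marginals, no grid materialised
  nu_s <- vapply(seq_along(classes), function(si) {
    v <- p_marg[[si]][[1]]
    for (c in seq_len(n_c)[-1]) {
      v <- as.numeric(outer(v, p_marg[[si]][[c]]))
    }
    v
  }, numeric(G))
  if (is.null(dim(nu_s))) nu_s <- matrix(nu_s, nrow = G)
  nu <- as.numeric(nu_s %*% ps)

  # observed joint distribution mapped onto the grid
  pr <- tabulate(row_id, nbins = G) / n_tr

  # I_ind: information of the conditionally-independent surrogate
  i_ind <- 0
  for (si in seq_along(classes)) {
    pos <- nu_s[, si] > 0
    i_ind <- i_ind + ps[si] *
      sum(nu_s[pos, si] * log2(nu_s[pos, si] / nu[pos]))
  }

  i_lin <- sum(vapply(seq_len(n_c), function(c) {
    plugin_mi(words[, c], labels)$value
  }, numeric(1)))
  i_sig_sim <- i_ind - i_lin

  pos <- nu > 0
  i_cor_ind <- -sum((pr[pos] - nu[pos]) * log2(nu[pos]))

  i_total <- plugin_mi(row_id, labels)$value
  i_cor_dep <- i_total - i_lin - i_sig_sim - i_cor_ind

  # direct evaluation of the stimulus-dependent term over observed words,
  # kept as a diagnostic cross-check of the residual form
  dep_direct <- 0
  for (si in seq_along(classes)) {
    tr <- labels == classes[si]
    cnt <- tabulate(row_id[tr], nbins = G)
    obs <- which(cnt > 0)
    prs <- cnt[obs] / sum(tr)
    dep_direct <- dep_direct + ps[si] *
      sum(prs * log2(prs * nu[obs] / (nu_s[obs, si] * pr[obs])))
  }

  new_breakdown(i_total, i_lin, i_sig_sim, i_cor_ind, i_cor_dep, "plugin",
                diagnostics = list(i_ind = i_ind,
                                   i_cor_dep_direct = dep_direct))
}

#' Pairwise stimulus-independent noise correlations
#'
#' Pearson correlation of the spike counts of each neuron pair across
#' repeated presentations of the same stimulus, averaged over stimulus
#' classes (weighted by class trial counts by default) and then over pairs.
#' Classes in which either neuron has zero count variance contribute as
#' missing for that pair.
#'
#' @param counts Trials x neurons matrix of spike counts.
#' @param labels Stimulus class per trial.
#' @param weighted Weight the per-class correlations by trial counts
#'   (default `TRUE`).
#' @return A `pairwise_noise_corr` object: `mean_r` plus a `pairs` tibble
#'   (`neuron_i`, `neuron_j`, `r`).
#' @export
pairwise_noise_correlation <- function(counts, labels, weighted = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_spikeinfo("need >= 2 neurons")
  classes <- unique(labels)
  if (any(table(labels) < 3)) {
    stop_spikeinfo("need >= 3 trials per stimulus class")
  }
  pair_idx <- utils::combn(ncol(counts), 2)
  pairs <- map(seq_len(ncol(pair_idx)), function(k) {
    i <- pair_idx[1, k]
    j <- pair_idx[2, k]
    rs <- vapply(classes, function(cl) {
      tr <- which(labels == cl)
      xi <- counts[tr, i]
      xj <- counts[tr, j]
      if (sd(xi) == 0 || sd(xj) == 0) NA_real_ else cor(xi, xj)
    }, numeric(1))
    w <- as.numeric(table(factor(labels, classes)))
    ok <- !is.na(rs)
    r <- if (!any(ok)) {
      NA_real_
    } else if (weighted) {
      sum(rs[ok] * w[ok]) / sum(w[ok])
    } else {
      mean(rs[ok])
    }
    tibble(neuron_i = i, neuron_j = j, r = r)
  }) |> bind_rows()
  structure(
    list(mean_r = mean(pairs$r, na.rm = TRUE),
         pairs = pairs, weighted = weighted),
    class = "pairwise_noise_corr"
  )
}

#' @export
print.pairwise_noise_corr <- function(x, ...) {
  cat(sprintf("<pairwise_noise_corr> mean r = %.4f over %d pairs\n",
              x$mean_r, nrow(x$pairs)))
  invisible(x)
}
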