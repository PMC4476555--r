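# Single-cell information ranking, ensemble-size information/decoding curves,
# redundancy, and matching of comparable INH / best-EXC groups.

#' Single-cell stimulus information
#'
#' Information each neuron individually carries about stimulus location,
#' using the binary principal-whisker versus neighbouring-whisker scheme:
#' trials deflecting the neuron's PW form one class, all other whiskers are
#' pooled as NW.
#'
#' @param session A [recording_session()] (source of the PW map).
#' @param tensor A [build_responses()] tensor from that session.
#' @param space `"pattern"` (default) or `"count"` response words.
#' @param method `"qe"` (default), `"plugin"` or `"jackknife"`.
#' @param neurons Neuron ids (default all in the tensor).
#' @param seed Seed for the QE partitioning.
#' @return Tibble: `neuron_id`, `layer`, `column`, `cell_type`, `info_bits`,
#'   `space`, `method`.
#' @export
single_cell_info <- function(session, tensor, space = "pattern",
                             method = "qe", neurons = NULL, seed = NULL) {
  neurons <- neurons %||% tensor$neuron_ids
  est <- function(words, labels, s) {
    switch(method,
      qe = qe_corrected_mi(words, labels, seed = s)$value,
      plugin = plugin_mi(words, labels)$value,
      jackknife = jackknife_mi(words, labels)$value,
      stop_spikeinfo(sprintf("unknown estimator '%s'", method)))
  }
  vals <- map_dbl(neurons, function(nid) {
    labels <- trial_labels(tensor, "pw_vs_nw", session = session, neuron = nid)
    words <- response_words(tensor, nid, space)
    est(words, labels, if (is.null(seed)) NULL else derive_seed(seed, nid))
  })
  session$neurons |>
    filter(.data$neuron_id %in% neurons) |>
    select("neuron_id", "layer", "column", "cell_type") |>
    left_join(tibble(neuron_id = neurons, info_bits = vals), by = "neuron_id") |>
    mutate(space = space, method = method)
}

#' Order neurons by their single-cell information
#'
#' @param info_tbl Tibble with `neuron_id` and `info_bits` (e.g. from
#'   [single_cell_info()]).
#' @param mode `"descending"` (most informative first) or `"ascending"`.
#'   Ties are broken by `neuron_id` ascending.
#' @return Integer vector of neuron ids.
#' @export
rank_neurons <- function(info_tbl, mode = c("descending", "ascending")) {
  mode <- match.arg(mode)
  ordered <- if (mode == "descending") {
    info_tbl |> arrange(desc(.data$info_bits), .data$neuron_id)
  } else {
    info_tbl |> arrange(.data$info_bits, .data$neuron_id)
  }
  ordered$neuron_id
}

#' Ensemble-size information or decoding curves
#'
#' Starting from the first neuron of `ordering` and adding one neuron at a
#' time, computes either the ensemble mutual information about the stimulus
#' (`measure = "ensemble_mi"`) or the cross-validated decoding performance
#' (`measure = "decoding_performance"`) at each size. For the information
#' measure the redundancy at size k is the ensemble information minus the
#' summed single-cell informations of its members (negative synergy =
#' redundancy). Pattern-based ensemble information is capped at
#' `max_pattern_neurons` neurons, where the estimates remain reliable; use
#' counts for larger groups.
#'
#' @param tensor A [build_responses()] tensor.
#' @param ordering Neuron ids, most- or least-informative first (see
#'   [rank_neurons()]).
#' @param measure `"ensemble_mi"` or `"decoding_performance"`.
#' @param space `"count"` (default) or `"pattern"` words.
#' @param estimator `"plugin"` or `"qe"` for the information measure.
#' @param labels Per-trial labels (default: stimulus location).
#' @param seed Seed (QE partitions / CV folds).
#' @param max_pattern_neurons Hard cap for pattern-based information.
#' @param n_folds,n_components Decoding parameters (see [lda_crossval()]).
#' @param order_mode Stored tag (`"descending"`/`"ascending"`/`"custom"`).
#' @return An `ensemble_curve`: tibble (`size`, `neuron_id`, `value`,
#'   `redundancy`) with attributes `measure`, `space`, `estimator`,
#'   `order_mode`, `ordering`.
#' @export
ensemble_curve <- function(tensor, ordering,
                           measure = c("ensemble_mi", "decoding_performance"),
                           space = "count", estimator = "plugin",
                           labels = NULL, seed = NULL,
                           max_pattern_neurons = 10, n_folds = 4,
                           n_components = 10, order_mode = "custom") {
  measure <- match.arg(measure)
  if (length(ordering) == 0) stop_spikeinfo("ordering is empty")
  labels <- labels %||% trial_labels(tensor, "location")
  if (measure == "ensemble_mi" && space == "pattern" &&
      length(ordering) > max_pattern_neurons) {
    stop_spikeinfo(sprintf(
      "pattern-based ensemble information is capped at %d neurons; use counts or a smaller group",
      max_pattern_neurons))
  }

  est <- function(words, s) {
    if (estimator == "qe") {
      qe_corrected_mi(words, labels, seed = s)$value
    } else {
      plugin_mi(words, labels)$value
    }
  }

  sizes <- seq_along(ordering)
  if (measure == "ensemble_mi") {
    singles <- map_dbl(seq_along(ordering), function(i) {
      est(response_words(tensor, ordering[i], space),
          if (is.null(seed)) NULL else derive_seed(seed, i, 1))
    })
    values <- map_dbl(sizes, function(k) {
      est(ensemble_words(tensor, ordering[seq_len(k)], space),
          if (is.null(seed)) NULL else derive_seed(seed, k, 1))
    })
    redundancy <- values - cumsum(singles)
  } else {
    feats <- tensor_features(tensor, ordering,
                             if (space == "count") "count" else "pattern")
    n_bins <- if (space == "count") 1 else tensor$n_bins
    values <- map_dbl(sizes, function(k) {
      cols <- seq_len(k * n_bins)
      lda_crossval(feats[, cols, drop = FALSE], labels, n_folds = n_folds,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, k, 2),
                   n_components = min(n_components, k * n_bins))$performance
    })
    redundancy <- rep(NA_real_, length(sizes))
  }

  out <- tibble(size = sizes, neuron_id = ordering, value = values,
                redundancy = redundancy)
  structure(out, class = c("ensemble_curve", class(out)),
            measure = measure, space = space, estimator = estimator,
            order_mode = order_mode, ordering = ordering)
}

#' Match comparable INH and best-EXC groups
#'
#' Two groups are comparable when they carry the same amount of ensemble
#' information. The INH group is the full set behind its descending-order
#' curve; the EXC group is the smallest prefix of the descending EXC curve
#' whose ensemble information reaches at least the INH group's total (minus
#' `epsilon` for noisy estimates). When no prefix reaches it, the full EXC
#' prefix is returned with `matched = FALSE`.
#'
#' @param inh_curve,exc_curve Descending-order `ensemble_mi`
#'   [ensemble_curve()]s.
#' @param epsilon Matching tolerance in bits (default 0).
#' @return A `group_match`: `inh_ids`, `exc_ids`, `inh_info`, `exc_info`,
#'   `matched`.
#' @export
match_comparable_groups <- function(inh_curve, exc_curve, epsilon = 0) {
  if (nrow(inh_curve) == 0 || nrow(exc_curve) == 0) {
    stop_spikeinfo("both groups must be non-empty")
  }
  inh_info <- inh_curve$value[nrow(inh_curve)]
  reach <- which(exc_curve$value >= inh_info - epsilon)
  if (length(reach) > 0) {
    k <- min(reach)
    matched <- TRUE
  } else {
    k <- nrow(exc_curve)
    matched <- FALSE
  }
  structure(
    list(inh_ids = attr(inh_curve, "ordering"),
         exc_ids = attr(exc_curve, "ordering")[seq_len(k)],
         inh_info = inh_info, exc_info = exc_curve$value[k],
         matched = matched),
    class = "group_match"
  )
}

#' @export
print.group_match <- function(x, ...) {
  cat(sprintf(
    "<group_match> %d INH (%.3f bits) vs %d best-EXC (%.3f bits)%s\n",
    length(x$inh_ids), x$inh_info, length(x$exc_ids), x$exc_info,
    if (x$matched) "" else " [not matched]"))
  invisible(x)
}

#' Per-session INH versus best-EXC redundancy report
#'
#' Assembles, for one session, the comparable-group match between the full
#' INH ensemble and the smallest equally informative best-EXC ensemble, the
#' information redundancy of both groups at their matched sizes, their
#' breakdown terms (signal similarity, stimulus-independent and -dependent
#' correlational components) and their mean pairwise noise correlations.
#' Ensemble quantities use spike counts; the ranking underlying the
#' descending orders uses single-cell information (see [single_cell_info()]).
#'
#' @param session A [recording_session()].
#' @param tensor A [build_responses()] tensor (typically low-frequency
#'   blocks, 50 ms window).
#' @param estimator `"plugin"` or `"qe"` for the ensemble-information curves
#'   (and hence the redundancy values).
#' @param breakdown_method Estimator for the breakdown terms (defaults to
#'   `estimator`; plug-in keeps the enumeration cheap for larger groups).
#' @param rank_space,rank_method Word space / estimator for the single-cell
#'   ranking (defaults: pattern words, QE).
#' @param seed Seed for all stochastic steps.
#' @return One-row tibble: group sizes, informations, redundancies,
#'   signal-similarity and correlational terms, mean noise correlations, and
#'   the matched flag.
#' @param curve_space Word space for the ensemble-information curves
#'   (default `"pattern"`, the space in which ensemble information is
#'   measured; groups are truncated to `max_pattern_neurons`).
#' @param max_pattern_neurons Cap on group sizes for pattern-based curves.
#' @export
redundancy_comparison <- function(session, tensor, estimator = "plugin",
                                  breakdown_method = estimator,
                                  rank_space = "pattern", rank_method = "qe",
                                  curve_space = "pattern",
                                  max_pattern_neurons = 10, seed = NULL) {
  types <- session$neurons$cell_type[match(tensor$neuron_ids,
                                           session$neurons$neuron_id)]
  inh_ids <- tensor$neuron_ids[types == "INH"]
  exc_ids <- tensor$neuron_ids[types == "EXC"]
  if (length(inh_ids) < 2 || length(exc_ids) < 2) {
    stop_spikeinfo("session must contain >= 2 neurons of each cell type")
  }
  info <- single_cell_info(session, tensor, space = rank_space,
                           method = rank_method, seed = seed)
  inh_order <- rank_neurons(info |> filter(.data$cell_type == "INH"))
  exc_order <- rank_neurons(info |> filter(.data$cell_type == "EXC"))
  if (curve_space == "pattern") {
    inh_order <- head(inh_order, max_pattern_neurons)
    exc_order <- head(exc_order, max_pattern_neurons)
  }

  labels <- trial_labels(tensor, "location")
  inh_curve <- ensemble_curve(tensor, inh_order, "ensemble_mi",
                              space = curve_space, estimator = estimator,
                              labels = labels, order_mode = "descending",
                              max_pattern_neurons = max_pattern_neurons,
                              seed = if (is.null(seed)) NULL else derive_seed(seed, 11))
  exc_curve <- ensemble_curve(tensor, exc_order, "ensemble_mi",
                              space = curve_space, estimator = estimator,
                              labels = labels, order_mode = "descending",
                              max_pattern_neurons = max_pattern_neurons,
                              seed = if (is.null(seed)) NULL else derive_seed(seed, 12))
  gm <- match_comparable_groups(inh_curve, exc_curve)

  group_terms <- function(ids) {
    wm <- word_matrix(tensor, ids, "count")
    bd <- breakdown(wm, labels,
                    method = if (breakdown_method == "qe") "qe" else "plugin",
                    seed = if (is.null(seed)) NULL else derive_seed(seed, 13))
    nc <- pairwise_noise_correlation(wm, labels)
    list(bd = bd, nc = nc)
  }
  g_inh <- group_terms(gm$inh_ids)
  g_exc <- group_terms(gm$exc_ids)

  tibble(
    session_id = session$session_id,
    n_inh = length(gm$inh_ids), n_exc = length(gm$exc_ids),
    inh_info = gm$inh_info, exc_info = gm$exc_info,
    inh_redundancy = inh_curve$redundancy[nrow(inh_curve)],
    exc_redundancy = exc_curve$redundancy[length(gm$exc_ids)],
    inh_sig_sim = g_inh$bd$i_sig_sim, exc_sig_sim = g_exc$bd$i_sig_sim,
    inh_cor_ind = g_inh$bd$i_cor_ind, exc_cor_ind = g_exc$bd$i_cor_ind,
    inh_cor_dep = g_inh$bd$i_cor_dep, exc_cor_dep = g_exc$bd$i_cor_dep,
    inh_noise_r = g_inh$nc$mean_r, exc_noise_r = g_exc$nc$mean_r,
    matched = gm$matched
  )
}
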