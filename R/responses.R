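#' Trial retention under the adaptation-exclusion rule
#'
#' Evoked spike counts decline over the first trials of stimulation blocks at
#' frequencies >= 4 Hz (sensory adaptation). All analyses therefore drop the
#' first `n_exclude` trials of such blocks; blocks below 4 Hz are kept whole.
#'
#' @param block One row of a session's `blocks` tibble (or a list with
#'   `onset_s` and `frequency_class`).
#' @param n_exclude Number of initial trials to drop at >= 4 Hz (default 20).
#' @return Integer vector of retained trial indices (1-based).
#' @export
exclude_adapted_trials <- function(block, n_exclude = 20) {
  onsets <- if (is.list(block$onset_s)) block$onset_s[[1]] else block$onset_s
  n_tr <- length(onsets)
  fc <- block$frequency_class[[1]]
  if (!is_adapting_frequency(fc)) {
    return(seq_len(n_tr))
  }
  if (n_tr <= n_exclude) {
    stop_spikeinfo(sprintf(
      "block at %s Hz has only %d trials; nothing left after dropping the first %d",
      fc, n_tr, n_exclude))
  }
  seq.int(n_exclude + 1L, n_tr)
}

#' Build per-trial spike counts and binned spike patterns
#'
#' Converts spike trains and stimulus onsets into the two response
#' representations used throughout: the spike count in a post-stimulus window
#' of `window_ms`, and the binary spike pattern obtained by splitting that
#' window into `window_ms / bin_ms` bins (a bin is 1 when it contains at
#' least one spike). Windows are anchored at stimulus onset and half-open.
#'
#' @param session A [recording_session()].
#' @param block_ids Blocks to include (default all).
#' @param window_ms Response window length (ms), must be divisible by
#'   `bin_ms`.
#' @param bin_ms Pattern bin size (ms).
#' @param exclude_adapted Apply [exclude_adapted_trials()] per block
#'   (default `TRUE`).
#' @param neuron_ids Neurons to include (default all).
#'
#' @return A `response_tensor`: list with `counts` (trials x neurons integer
#'   matrix), `patterns` (trials x neurons x n_bins binary array),
#'   `trial_info` (tibble: `block_id`, `stimulus_id`, `frequency_class`,
#'   `onset_s`), `neuron_ids`, `window_ms`, `bin_ms`, `n_bins`.
#' @export
build_responses <- function(session, block_ids = NULL, window_ms = 50,
                            bin_ms = 5, exclude_adapted = TRUE,
                            neuron_ids = NULL) {
  stopifnot(inherits(session, "recording_session"))
  n_bins <- window_ms / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop_spikeinfo("window_ms must be divisible by bin_ms")
  }
  n_bins <- as.integer(round(n_bins))
  block_ids <- block_ids %||% session$blocks$block_id
  neuron_ids <- neuron_ids %||% session$neurons$neuron_id
  nrow_idx <- match(neuron_ids, session$neurons$neuron_id)
  if (anyNA(nrow_idx)) stop_spikeinfo("unknown neuron_ids requested")

  w_s <- window_ms / 1000
  bin_s <- bin_ms / 1000

  info_list <- list()
  onset_list <- list()
  for (bid in block_ids) {
    b <- which(session$blocks$block_id == bid)
    if (length(b) != 1) stop_spikeinfo(sprintf("unknown block_id %s", bid))
    onsets <- session$blocks$onset_s[[b]]
    keep <- if (exclude_adapted) {
      exclude_adapted_trials(session$blocks[b, ])
    } else {
      seq_along(onsets)
    }
    onsets <- onsets[keep]
    if (length(onsets) > 1 && w_s > min(diff(onsets)) + 1e-12) {
      stop_spikeinfo(sprintf(
        "response window (%g ms) overlaps the next onset in block %s",
        window_ms, bid))
    }
    onset_list[[length(onset_list) + 1]] <- onsets
    info_list[[length(info_list) + 1]] <- tibble(
      block_id = session$blocks$block_id[b],
      stimulus_id = session$blocks$stimulus_id[b],
      frequency_class = session$blocks$frequency_class[b],
      trial_in_block = keep,
      onset_s = onsets
    )
  }
  trial_info <- bind_rows(info_list)
  n_trials <- nrow(trial_info)
  n_neur <- length(neuron_ids)

  counts <- matrix(0L, n_trials, n_neur)
  patterns <- array(0L, dim = c(n_trials, n_neur, n_bins))

  row_offset <- 0L
  for (k in seq_along(onset_list)) {
    onsets <- onset_list[[k]]
    n_tr <- length(onsets)
    rows <- row_offset + seq_len(n_tr)
    for (j in seq_len(n_neur)) {
      st <- session$neurons$spike_times[[nrow_idx[j]]]
      if (length(st) == 0) next
      counts[rows, j] <- counts[rows, j] +
        as.integer(n_below(onsets + w_s, st) - n_below(onsets, st))
      # locate spikes within windows: trial index from sorted onsets
      tr <- findInterval(st, onsets)
      in_win <- tr > 0 & st < onsets[pmax(tr, 1)] + w_s & st >= onsets[pmax(tr, 1)]
      if (any(in_win)) {
        tr_i <- tr[in_win]
        bin_i <- pmin(floor((st[in_win] - onsets[tr_i]) / bin_s), n_bins - 1)
        patterns[cbind(row_offset + tr_i, j, bin_i + 1)] <- 1L
      }
    }
    row_offset <- row_offset + n_tr
  }

  structure(
    list(counts = counts, patterns = patterns, trial_info = trial_info,
         neuron_ids = neuron_ids, window_ms = window_ms, bin_ms = bin_ms,
         n_bins = n_bins, shuffled = FALSE),
    class = "response_tensor"
  )
}

#' @export
print.response_tensor <- function(x, ...) {
  cat(sprintf(
    "<response_tensor> %d trials x %d neurons, %g ms window / %g ms bins (%d bins)%s\n",
    nrow(x$counts), ncol(x$counts), x$window_ms, x$bin_ms, x$n_bins,
    if (isTRUE(x$shuffled)) " [trial-shuffled]" else ""))
  invisible(x)
}

#' Per-neuron discrete response words
#'
#' Encodes each trial's response of one neuron as a discrete symbol: the raw
#' spike count (`space = "count"`) or the binary spike pattern packed into an
#' integer word (`space = "pattern"`, alphabet size `2^n_bins`).
#'
#' @param tensor A [build_responses()] tensor.
#' @param neuron Column index or neuron id (matched against `neuron_ids`).
#' @param space `"count"` or `"pattern"`.
#' @return Integer vector with one word per trial.
#' @export
response_words <- function(tensor, neuron, space = c("count", "pattern")) {
  space <- match.arg(space)
  j <- if (neuron %in% tensor$neuron_ids) {
    match(neuron, tensor$neuron_ids)
  } else {
    neuron
  }
  if (space == "count") {
    tensor$counts[, j]
  } else {
    pw2 <- 2^(seq_len(tensor$n_bins) - 1)
    pm <- matrix(tensor$patterns[, j, ], ncol = tensor$n_bins)
    as.integer(pm %*% pw2)
  }
}

#' Ensemble response words
#'
#' Serialises the joint response of a set of neurons on each trial into one
#' opaque word (dictionary built from observed words only).
#'
#' @inheritParams response_words
#' @param neurons Vector of neuron ids / column indices (default all).
#' @return Character vector with one joint word per trial.
#' @export
ensemble_words <- function(tensor, neurons = NULL,
                           space = c("count", "pattern")) {
  space <- match.arg(space)
  neurons <- neurons %||% tensor$neuron_ids
  mat <- vapply(neurons, function(nn) response_words(tensor, nn, space),
                integer(nrow(tensor$counts)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  apply(mat, 1, paste, collapse = ",")
}

#' Trials x neurons matrix of per-neuron response words
#'
#' Convenience builder for [breakdown()] and [linear_term()]: column `c`
#' holds neuron `c`'s discrete word on every trial.
#'
#' @inheritParams ensemble_words
#' @return Integer matrix, trials x neurons.
#' @export
word_matrix <- function(tensor, neurons = NULL, space = "count") {
  neurons <- neurons %||% tensor$neuron_ids
  mat <- vapply(neurons, function(nn) response_words(tensor, nn, space),
                integer(nrow(tensor$counts)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(neurons))
  mat
}

#' Per-trial stimulus labels for a tensor
#'
#' Three labelling schemes are used by the analyses: `"location"` labels each
#' trial with the deflected whisker (ensemble analyses, 2--3 classes);
#' `"frequency"` labels each trial with its block's frequency class, pooling
#' only the blocks of one whisker (pass `stimulus`); `"pw_vs_nw"` is the
#' single-cell scheme, labelling trials as `"PW"` when the deflected whisker
#' is the given neuron's principal whisker and `"NW"` otherwise.
#'
#' @param tensor A [build_responses()] tensor.
#' @param scheme `"location"`, `"frequency"` or `"pw_vs_nw"`.
#' @param session Required for `"pw_vs_nw"` (source of the PW map).
#' @param neuron Neuron id for `"pw_vs_nw"`.
#' @param stimulus Whisker id for `"frequency"`; trials of other whiskers get
#'   `NA` (drop them before estimating).
#' @return Character vector of labels, one per trial.
#' @export
trial_labels <- function(tensor, scheme = c("location", "frequency", "pw_vs_nw"),
                         session = NULL, neuron = NULL, stimulus = NULL) {
  scheme <- match.arg(scheme)
  ti <- tensor$trial_info
  switch(scheme,
    location = ti$stimulus_id,
    frequency = {
      out <- ti$frequency_class
      if (!is.null(stimulus)) out[ti$stimulus_id != stimulus] <- NA_character_
      out
    },
    pw_vs_nw = {
      if (is.null(session) || is.null(neuron)) {
        stop_spikeinfo("pw_vs_nw labels need `session` and `neuron`")
      }
      pw <- session$principal_whisker_map[[as.character(neuron)]]
      if (is.null(pw)) {
        stop_spikeinfo(sprintf("no principal whisker recorded for neuron %s",
                               neuron))
      }
      ifelse(ti$stimulus_id == pw, "PW", "NW")
    }
  )
}

#' Response summaries per neuron and stimulus
#'
#' Mean spike count, median first-spike latency (over trials with at least
#' one spike in the window; missing when no trial has one) and a
#' peri-stimulus time histogram at `psth_bin_ms` resolution.
#'
#' @param session A [recording_session()].
#' @param tensor A [build_responses()] tensor from the same session.
#' @param psth_bin_ms PSTH resolution in ms (default 2.5).
#' @return Tibble with one row per (neuron, stimulus): `neuron_id`,
#'   `stimulus_id`, `n_trials`, `mean_count`, `median_latency_ms`, and a
#'   `psth` list-column of tibbles (`time_ms`, `rate_hz`).
#' @export
summarize_responses <- function(session, tensor, psth_bin_ms = 2.5) {
  stopifnot(inherits(tensor, "response_tensor"))
  ti <- tensor$trial_info
  w_s <- tensor$window_ms / 1000
  psth_bin_s <- psth_bin_ms / 1000
  n_psth <- ceiling(tensor$window_ms / psth_bin_ms)
  stims <- unique(ti$stimulus_id)

  rows <- list()
  for (j in seq_along(tensor$neuron_ids)) {
    nid <- tensor$neuron_ids[j]
    st <- session$neurons$spike_times[[match(nid, session$neurons$neuron_id)]]
    for (s in stims) {
      tr <- which(ti$stimulus_id == s)
      onsets <- ti$onset_s[tr]
      lat <- vapply(onsets, function(o) {
        k <- n_below(o, st) + 1
        if (k <= length(st) && st[k] < o + w_s) (st[k] - o) * 1000 else NA_real_
      }, numeric(1))
      rel <- unlist(lapply(onsets, function(o) {
        sel <- st[st >= o & st < o + w_s]
        sel - o
      }))
      psth_counts <- tabulate(pmin(floor(rel / psth_bin_s), n_psth - 1) + 1,
                              nbins = n_psth)
      psth <- tibble(
        time_ms = (seq_len(n_psth) - 0.5) * psth_bin_ms,
        rate_hz = psth_counts / (length(tr) * psth_bin_s)
      )
      rows[[length(rows) + 1]] <- tibble(
        neuron_id = nid, stimulus_id = s, n_trials = length(tr),
        mean_count = mean(tensor$counts[tr, j]),
        median_latency_ms = if (all(is.na(lat))) NA_real_ else
          median(lat, na.rm = TRUE),
        psth = list(psth)
      )
    }
  }
  bind_rows(rows)
}
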