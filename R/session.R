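#' Assemble a recording session
#'
#' A recording session bundles the spike trains and metadata of simultaneously
#' recorded neurons with the stimulus protocol (blocks of whisker deflections)
#' applied during the recording. It is the container every analysis stage
#' consumes.
#'
#' @param neurons Tibble with one row per neuron and columns `neuron_id`
#'   (integer, unique), `layer` (one of `"L2/3"`, `"L4"`, `"L5A"`, `"L5B/6"`),
#'   `column` (barrel label, e.g. `"D1"`), `cell_type` (`"INH"`, `"EXC"` or
#'   `"UNCLASSIFIED"`), `trough_to_peak_ms` (> 0), `asymmetry` (in \[-1, 1\]),
#'   and `spike_times` (list-column of sorted spike times in seconds).
#' @param blocks Tibble with one row per stimulation block and columns
#'   `block_id` (integer, unique), `stimulus_id` (whisker label),
#'   `frequency_class` (one of `"<1"`, `"1"`, `"2"`, `"4"`, `"7"`, `"10"` Hz)
#'   and `onset_s` (list-column of strictly increasing trial onset times in
#'   seconds). For periodic blocks (>= 1 Hz) consecutive onsets must be spaced
#'   by 1/f within `spacing_tol`.
#' @param principal_whisker_map Named character vector mapping neuron ids
#'   (names) to the stimulus id of their principal whisker.
#' @param session_id Character identifier for the session.
#' @param duration_s Total recording duration in seconds. Defaults to the last
#'   event observed (spike or onset + 1 s).
#' @param spacing_tol Relative tolerance on the inter-onset spacing of
#'   periodic blocks (default 0.05).
#'
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(neurons, blocks, principal_whisker_map = NULL,
                              session_id = "session", duration_s = NULL,
                              spacing_tol = 0.05) {
  neurons <- as_tibble(neurons)
  blocks <- as_tibble(blocks)

  needed_n <- c("neuron_id", "layer", "column", "cell_type",
                "trough_to_peak_ms", "asymmetry", "spike_times")
  missing_n <- setdiff(needed_n, names(neurons))
  if (length(missing_n) > 0) {
    stop_spikeinfo(paste0("neurons table is missing column(s): ",
                          paste(missing_n, collapse = ", ")),
                   class = "spikeinfo_format_error")
  }
  needed_b <- c("block_id", "stimulus_id", "frequency_class", "onset_s")
  missing_b <- setdiff(needed_b, names(blocks))
  if (length(missing_b) > 0) {
    stop_spikeinfo(paste0("blocks table is missing column(s): ",
                          paste(missing_b, collapse = ", ")),
                   class = "spikeinfo_format_error")
  }

  if (anyDuplicated(neurons$neuron_id)) {
    stop_spikeinfo("neuron_id values must be unique")
  }
  if (anyDuplicated(blocks$block_id)) {
    stop_spikeinfo("block_id values must be unique")
  }
  bad_type <- setdiff(unique(neurons$cell_type), CELL_TYPES)
  if (length(bad_type) > 0) {
    stop_spikeinfo(paste0("unknown cell_type: ", paste(bad_type, collapse = ", ")))
  }
  if (any(!is.finite(neurons$trough_to_peak_ms) | neurons$trough_to_peak_ms <= 0)) {
    stop_spikeinfo("trough_to_peak_ms must be finite and > 0")
  }
  if (any(!is.finite(neurons$asymmetry) | abs(neurons$asymmetry) > 1)) {
    stop_spikeinfo("asymmetry must be finite and within [-1, 1]")
  }
  for (i in seq_len(nrow(neurons))) {
    st <- neurons$spike_times[[i]]
    if (length(st) > 0 && is.unsorted(st)) {
      stop_spikeinfo(sprintf("spike times of neuron %s are not sorted",
                             neurons$neuron_id[i]),
                     class = "spikeinfo_validation_error")
    }
  }
  bad_freq <- setdiff(unique(blocks$frequency_class), FREQ_CLASSES)
  if (length(bad_freq) > 0) {
    stop_spikeinfo(paste0("unknown frequency_class: ",
                          paste(bad_freq, collapse = ", ")))
  }
  for (i in seq_len(nrow(blocks))) {
    on <- blocks$onset_s[[i]]
    if (length(on) == 0) {
      stop_spikeinfo(sprintf("block %s has no trials", blocks$block_id[i]))
    }
    if (length(on) > 1 && any(diff(on) <= 0)) {
      stop_spikeinfo(sprintf("onsets of block %s are not strictly increasing",
                             blocks$block_id[i]),
                     class = "spikeinfo_validation_error")
    }
    f <- freq_hz(blocks$frequency_class[i])
    if (!is.na(f) && length(on) > 1) {
      rel_err <- abs(diff(on) - 1 / f) * f
      if (any(rel_err > spacing_tol)) {
        stop_spikeinfo(sprintf(
          "block %s: inter-onset spacing deviates from 1/%g s by more than %g%%",
          blocks$block_id[i], f, 100 * spacing_tol),
          class = "spikeinfo_validation_error")
      }
    }
  }
  if (!is.null(principal_whisker_map)) {
    unknown <- setdiff(names(principal_whisker_map),
                       as.character(neurons$neuron_id))
    if (length(unknown) > 0) {
      stop_spikeinfo(paste0("principal_whisker_map refers to unknown neurons: ",
                            paste(unknown, collapse = ", ")))
    }
    bad_stim <- setdiff(unique(principal_whisker_map), unique(blocks$stimulus_id))
    if (length(bad_stim) > 0) {
      stop_spikeinfo(paste0("principal_whisker_map refers to stimuli absent ",
                            "from the blocks: ", paste(bad_stim, collapse = ", ")))
    }
  }

  if (is.null(duration_s)) {
    last_spike <- suppressWarnings(max(c(0, unlist(neurons$spike_times))))
    last_onset <- suppressWarnings(max(c(0, unlist(blocks$onset_s)))) + 1
    duration_s <- max(last_spike, last_onset)
  }

  structure(
    list(
      session_id = session_id,
      neurons = neurons,
      blocks = blocks,
      principal_whisker_map = principal_whisker_map,
      duration_s = duration_s
    ),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session '%s'>\n", x$session_id))
  cat(sprintf("  %d neurons (%d INH, %d EXC), %d blocks, %.0f s\n",
              nrow(x$neurons),
              sum(x$neurons$cell_type == "INH"),
              sum(x$neurons$cell_type == "EXC"),
              nrow(x$blocks), x$duration_s))
  invisible(x)
}

#' Classify neurons as putative inhibitory or excitatory
#'
#' Extracellularly recorded neurons are labelled from their mean spike
#' waveform: narrow-spiking cells (short trough-to-peak latency) are putative
#' inhibitory interneurons, broad-spiking cells putative excitatory. The
#' boundary is a configurable line in the (trough-to-peak, asymmetry) plane;
#' the default is a pure trough-to-peak threshold at 0.30 ms, with the
#' boundary value itself assigned to the broader-spiking (EXC) class.
#'
#' @param trough_to_peak_ms Numeric vector of trough-to-peak latencies (ms).
#' @param asymmetry Numeric vector of waveform asymmetries in \[-1, 1\].
#' @param boundary List with elements `threshold_ms` (default 0.30) and
#'   `asymmetry_coef` (default 0): a neuron is INH when
#'   `trough_to_peak_ms + asymmetry_coef * asymmetry < threshold_ms`.
#'
#' @return Character vector of `"INH"` / `"EXC"` labels.
#' @export
#' @examples
#' classify_neuron(c(0.20, 0.41), c(-0.10, -0.34))
classify_neuron <- function(trough_to_peak_ms, asymmetry,
                            boundary = list(threshold_ms = 0.30,
                                            asymmetry_coef = 0)) {
  if (any(!is.finite(trough_to_peak_ms)) || any(!is.finite(asymmetry))) {
    stop_spikeinfo("waveform features must be finite")
  }
  score <- trough_to_peak_ms + boundary$asymmetry_coef * asymmetry
  ifelse(score < boundary$threshold_ms, "INH", "EXC")
}

#' Spontaneous firing rates
#'
#' Mean firing rate over the whole recording, excluding a window after every
#' stimulus onset (default 1 s) so that evoked spikes do not inflate the
#' estimate: spikes falling in any `[onset, onset + exclusion_window_s)`
#' interval are discarded and the excluded time is removed from the
#' denominator.
#'
#' @param session A [recording_session()].
#' @param neuron_ids Neurons to evaluate (default all).
#' @param exclusion_window_s Post-stimulus exclusion window in seconds.
#'
#' @return Tibble with columns `neuron_id` and `spontaneous_rate_hz`.
#' @export
spontaneous_rate <- function(session, neuron_ids = NULL,
                             exclusion_window_s = 1) {
  stopifnot(inherits(session, "recording_session"))
  onsets <- sort(unlist(session$blocks$onset_s))
  excl_start <- pmin(onsets, session$duration_s)
  excl_end <- pmin(onsets + exclusion_window_s, session$duration_s)
  keep_iv <- excl_end > excl_start
  excluded_time <- interval_union_length(excl_start[keep_iv],
                                         excl_end[keep_iv])
  free_time <- session$duration_s - excluded_time
  if (free_time <= 0) {
    stop_spikeinfo("no recording time left outside the exclusion windows")
  }
  ids <- neuron_ids %||% session$neurons$neuron_id
  rows <- match(ids, session$neurons$neuron_id)
  rate <- vapply(rows, function(i) {
    st <- session$neurons$spike_times[[i]]
    if (length(st) == 0) return(0)
    if (length(onsets) > 0) {
      # spikes inside any exclusion interval
      k <- findInterval(st, onsets)
      inside <- k > 0 & st < onsets[pmax(k, 1)] + exclusion_window_s & st >= onsets[pmax(k, 1)]
      n_free <- sum(!inside & st < session$duration_s)
    } else {
      n_free <- sum(st < session$duration_s)
    }
    n_free / free_time
  }, numeric(1))
  tibble(neuron_id = ids, spontaneous_rate_hz = rate)
}
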