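# Tab-separated on-disk representation of a recording session:
#   spikes.tsv  : neuron_id, spike_time_s
#   events.tsv  : block_id, stimulus_id, frequency_class, onset_s
#   neurons.tsv : neuron_id, layer, column, cell_type, trough_to_peak_ms, asymmetry
#   session.json: session_id, principal_whisker_map, duration_s

check_header <- function(df, needed, file) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_spikeinfo(sprintf("%s is missing column(s): %s", file,
                           paste(missing, collapse = ", ")),
                   class = "spikeinfo_format_error")
  }
}

#' Read a recording session from tab-separated tables
#'
#' @param spikes_path TSV with columns `neuron_id`, `spike_time_s`; within each
#'   neuron the spike times must appear in non-decreasing order.
#' @param events_path TSV with columns `block_id`, `stimulus_id`,
#'   `frequency_class`, `onset_s`.
#' @param neurons_path TSV with columns `neuron_id`, `layer`, `column`,
#'   `cell_type`, `trough_to_peak_ms`, `asymmetry` (`NA` allowed for
#'   `cell_type`, stored as `"UNCLASSIFIED"`).
#' @param meta_path Optional JSON sidecar with `session_id`,
#'   `principal_whisker_map` and `duration_s`.
#'
#' @return A [recording_session()].
#' @export
read_session <- function(spikes_path, events_path, neurons_path,
                         meta_path = NULL) {
  spikes <- readr::read_tsv(spikes_path, show_col_types = FALSE,
                            progress = FALSE)
  events <- readr::read_tsv(events_path, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(
                              frequency_class = readr::col_character(),
                              .default = readr::col_guess()))
  neurons_tbl <- readr::read_tsv(neurons_path, show_col_types = FALSE,
                                 progress = FALSE)

  check_header(spikes, c("neuron_id", "spike_time_s"), "spikes table")
  check_header(events, c("block_id", "stimulus_id", "frequency_class",
                         "onset_s"), "events table")
  check_header(neurons_tbl, c("neuron_id", "layer", "column", "cell_type",
                              "trough_to_peak_ms", "asymmetry"),
               "neurons table")

  unknown <- setdiff(unique(spikes$neuron_id), neurons_tbl$neuron_id)
  if (length(unknown) > 0) {
    stop_spikeinfo(paste0("spikes table references neuron_id(s) absent from ",
                          "the neurons table: ",
                          paste(unknown, collapse = ", ")),
                   class = "spikeinfo_validation_error")
  }
  for (id in unique(spikes$neuron_id)) {
    st <- spikes$spike_time_s[spikes$neuron_id == id]
    if (is.unsorted(st)) {
      stop_spikeinfo(sprintf("spike times of neuron %s are not sorted", id),
                     class = "spikeinfo_validation_error")
    }
  }

  spike_lists <- split(spikes$spike_time_s, spikes$neuron_id)
  neurons_tbl <- neurons_tbl |>
    mutate(
      cell_type = ifelse(is.na(.data$cell_type), "UNCLASSIFIED",
                         .data$cell_type),
      spike_times = map(as.character(.data$neuron_id),
                        ~ spike_lists[[.x]] %||% numeric(0))
    )

  blocks <- events |>
    group_by(.data$block_id, .data$stimulus_id, .data$frequency_class) |>
    summarise(onset_s = list(sort(.data$onset_s)), .groups = "drop") |>
    arrange(.data$block_id)

  session_id <- "session"
  pw_map <- NULL
  duration_s <- NULL
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    session_id <- meta$session_id %||% session_id
    duration_s <- meta$duration_s
    if (!is.null(meta$principal_whisker_map)) {
      pw_map <- unlist(meta$principal_whisker_map)
    }
  }

  recording_session(neurons_tbl, blocks, principal_whisker_map = pw_map,
                    session_id = session_id, duration_s = duration_s)
}

#' Write a recording session to tab-separated tables
#'
#' Inverse of [read_session()]: writes `spikes.tsv`, `events.tsv`,
#' `neurons.tsv` and `session.json` into `dir`.
#'
#' @param session A [recording_session()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  spikes <- session$neurons |>
    select("neuron_id", "spike_times") |>
    tidyr::unnest_longer("spike_times", values_to = "spike_time_s",
                         keep_empty = FALSE)
  readr::write_tsv(spikes, file.path(dir, "spikes.tsv"), progress = FALSE)

  events <- session$blocks |>
    tidyr::unnest_longer("onset_s")
  readr::write_tsv(events, file.path(dir, "events.tsv"), progress = FALSE)

  neurons_out <- session$neurons |>
    select("neuron_id", "layer", "column", "cell_type", "trough_to_peak_ms",
           "asymmetry") |>
    mutate(cell_type = ifelse(.data$cell_type == "UNCLASSIFIED",
                              NA_character_, .data$cell_type))
  readr::write_tsv(neurons_out, file.path(dir, "neurons.tsv"),
                   progress = FALSE)

  meta <- list(session_id = session$session_id,
               duration_s = session$duration_s,
               principal_whisker_map = as.list(
                 session$principal_whisker_map %||% list()))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
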