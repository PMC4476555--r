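# ggplot2 display layers (thin; not part of the numerical pipeline)

#' @export
autoplot.ensemble_curve <- function(object, ...) {
  ylab <- if (attr(object, "measure") == "ensemble_mi") {
    "Ensemble information (bits)"
  } else {
    "Decoding performance (% correct)"
  }
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$size, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Ensemble size (neurons)", y = ylab,
                  title = sprintf("%s order", attr(object, "order_mode"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decoded, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Decoded stimulus", y = "True stimulus",
                  title = sprintf("%.1f%% correct", object$performance)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.breakdown_terms <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$term %in% c("i_lin", "i_sig_sim", "i_cor_ind", "i_cor_dep"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$bits)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Information (bits)",
                  title = sprintf("Total: %.3f bits", object$i_total)) +
    ggplot2::theme_minimal()
}

#' Peri-stimulus time histograms of one neuron
#'
#' @param summaries Output of [summarize_responses()].
#' @param neuron Neuron id to plot.
#' @return A ggplot object (one PSTH line per stimulus).
#' @export
plot_psth <- function(summaries, neuron) {
  df <- summaries |>
    filter(.data$neuron_id == neuron) |>
    select("stimulus_id", "psth") |>
    tidyr::unnest("psth")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$rate_hz,
                                   colour = .data$stimulus_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time after deflection (ms)", y = "Rate (Hz)",
                  colour = "Stimulus") +
    ggplot2::theme_minimal()
}
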