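# broom-style tidiers for the package's result objects

#' @export
tidy.info_estimate <- function(x, ...) {
  tibble(value_bits = x$value, method = x$method,
         n_trials = x$n_trials_used, response_space = x$response_space,
         h_response = x$h_response, h_noise = x$h_noise)
}

#' @export
glance.info_estimate <- function(x, ...) tidy(x)

#' @export
tidy.breakdown_terms <- function(x, ...) {
  tibble(
    term = c("i_total", "i_lin", "synergy", "i_sig_sim", "i_cor",
             "i_cor_ind", "i_cor_dep"),
    bits = c(x$i_total, x$i_lin, x$synergy, x$i_sig_sim, x$i_cor,
             x$i_cor_ind, x$i_cor_dep)
  )
}

#' @export
glance.breakdown_terms <- function(x, ...) {
  tibble(i_total = x$i_total, i_lin = x$i_lin, synergy = x$synergy,
         i_sig_sim = x$i_sig_sim, i_cor_ind = x$i_cor_ind,
         i_cor_dep = x$i_cor_dep, method = x$method)
}

#' @export
tidy.decoding_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion))) |>
    rename(n = "Freq")
}

#' @export
glance.decoding_result <- function(x, ...) {
  tibble(performance = x$performance,
         mean_fold_performance = mean(x$fold_performance),
         transmitted_bits = x$transmitted_bits,
         chance_level = x$chance_level,
         n_components_used = x$n_components_used,
         shuffled = x$shuffled)
}

#' @export
tidy.test_result <- function(x, ...) {
  tibble(test = x$test_name, statistic = x$statistic, p_value = x$p_value,
         n_x = x$n[1], n_y = x$n[2], paired = x$paired,
         degenerate = x$degenerate)
}

#' @export
tidy.pairwise_noise_corr <- function(x, ...) x$pairs

#' @export
glance.pairwise_noise_corr <- function(x, ...) {
  tibble(mean_r = x$mean_r, n_pairs = nrow(x$pairs), weighted = x$weighted)
}

#' @export
tidy.ensemble_curve <- function(x, ...) {
  tibble(size = x$size, neuron_id = x$neuron_id, value = x$value,
         redundancy = x$redundancy,
         measure = attr(x, "measure"), order_mode = attr(x, "order_mode"))
}

#' @export
tidy.group_match <- function(x, ...) {
  tibble(n_inh = length(x$inh_ids), n_exc = length(x$exc_ids),
         inh_info = x$inh_info, exc_info = x$exc_info, matched = x$matched)
}

#' @export
tidy.shuffle_gain_analysis <- function(x, ...) x$table

#' @export
glance.shuffle_gain_analysis <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n_points = nrow(x$table))
}
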