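#' Configuration for the synthetic session generator
#'
#' Defines the stimulation protocol and response statistics of a simulated
#' multi-whisker deflection experiment: per whisker, one low-frequency block
#' (irregular 5--30 s intervals) of `trials_low` trials and one block of
#' `trials_high` trials per periodic frequency; Poisson evoked counts tuned to
#' each neuron's principal whisker (PW) with weaker, later responses to
#' neighbouring whiskers (NWs); multiplicative adaptation over early trials at
#' >= 4 Hz; an optional log-normal gain shared by all neurons within a trial
#' (the noise-correlation knob); and homogeneous-Poisson spontaneous firing.
#'
#' @param n_neurons Number of neurons.
#' @param inh_fraction Proportion of putative inhibitory neurons.
#' @param layer_mix Named proportions over the four layers (summing to 1).
#' @param whiskers Character vector of 2--3 whisker labels; adjacency is
#'   first-order along this vector.
#' @param trials_low,trials_high Trials per low-frequency / periodic block.
#' @param frequencies Subset of `c("<1","1","2","4","7","10")` (Hz).
#' @param pw_mean_count Named (INH, EXC) mean evoked spikes per trial for PW
#'   deflections at low frequency.
#' @param layer_gain Named multiplicative gain on `pw_mean_count` per layer.
#' @param nw_count_ratio NW/PW mean-count ratio in \[0, 1\] for informative
#'   neurons (uninformative EXC neurons always use 1, i.e. no contrast).
#' @param pw_latency_ms Base first-spike latency after PW deflection (ms).
#' @param nw_latency_offset_ms Additional latency for NW responses (ms).
#' @param jitter_sd_ms Named (INH, EXC) SD of the half-normal latency jitter.
#' @param adaptation_floor,adaptation_tau Floor (proportion) and trial
#'   constant of the exponential adaptation applied at >= 4 Hz.
#' @param spont_rate_hz Named (INH, EXC) spontaneous rates.
#' @param informative_exc_fraction Proportion of EXC neurons with PW/NW
#'   contrast (the "best EXC" minority).
#' @param informative_exc_gain Multiplier on `pw_mean_count` for informative
#'   EXC neurons (default 2), making the informative minority highly
#'   informative, as in recorded populations where the best excitatory cells
#'   rival inhibitory ones.
#' @param exc_shared_template If `TRUE` (default) all informative EXC neurons
#'   share the first whisker as PW (shared tuning template) while INH neurons
#'   get PWs round-robin across whiskers (heterogeneous templates).
#' @param shared_gain_sd SD of the trial-shared log-gain (0 = independent
#'   neurons given the stimulus).
#' @param seed Integer master seed; per-neuron and per-block sub-streams are
#'   derived from it, so enlarging the population does not perturb existing
#'   neurons.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_neurons = 20,
                         inh_fraction = 0.142,
                         layer_mix = c("L2/3" = 0.3, "L4" = 0.3,
                                       "L5A" = 0.2, "L5B/6" = 0.2),
                         whiskers = c("C1", "D1"),
                         trials_low = 200,
                         trials_high = 100,
                         frequencies = c("<1", "1", "2", "4", "7", "10"),
                         pw_mean_count = c(INH = 0.8, EXC = 0.35),
                         layer_gain = c("L2/3" = 0.8, "L4" = 1.2,
                                        "L5A" = 1.0, "L5B/6" = 0.9),
                         nw_count_ratio = 0.5,
                         pw_latency_ms = 8,
                         nw_latency_offset_ms = 5,
                         jitter_sd_ms = c(INH = 2, EXC = 5),
                         adaptation_floor = 0.4,
                         adaptation_tau = 7,
                         spont_rate_hz = c(INH = 5, EXC = 1),
                         informative_exc_fraction = 0.2,
                         informative_exc_gain = 2,
                         exc_shared_template = TRUE,
                         shared_gain_sd = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  prop_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  if (cfg$n_neurons < 1) stop_spikeinfo("n_neurons must be positive")
  if (!prop_ok(cfg$inh_fraction)) stop_spikeinfo("inh_fraction must be in [0, 1]")
  if (!prop_ok(cfg$nw_count_ratio)) stop_spikeinfo("nw_count_ratio must be in [0, 1]")
  if (!prop_ok(cfg$adaptation_floor)) stop_spikeinfo("adaptation_floor must be in [0, 1]")
  if (!prop_ok(cfg$informative_exc_fraction)) {
    stop_spikeinfo("informative_exc_fraction must be in [0, 1]")
  }
  if (abs(sum(cfg$layer_mix) - 1) > 1e-6) stop_spikeinfo("layer_mix must sum to 1")
  if (length(cfg$frequencies) == 0) stop_spikeinfo("frequencies must be non-empty")
  bad <- setdiff(cfg$frequencies, FREQ_CLASSES)
  if (length(bad) > 0) {
    stop_spikeinfo(paste0("unknown frequencies: ", paste(bad, collapse = ", ")))
  }
  if (length(cfg$whiskers) < 2 || length(cfg$whiskers) > 3) {
    stop_spikeinfo("whiskers must list 2 or 3 labels")
  }
  if (cfg$trials_low < 1 || cfg$trials_high < 1) {
    stop_spikeinfo("trial counts must be positive")
  }
  if (any(cfg$pw_mean_count < 0) || any(cfg$spont_rate_hz < 0)) {
    stop_spikeinfo("rates and mean counts must be non-negative")
  }
  if (cfg$adaptation_tau <= 0) stop_spikeinfo("adaptation_tau must be positive")
  if (cfg$informative_exc_gain < 0) {
    stop_spikeinfo("informative_exc_gain must be >= 0")
  }
  if (cfg$shared_gain_sd < 0) stop_spikeinfo("shared_gain_sd must be >= 0")
  invisible(cfg)
}

# first-order adjacency along the whisker vector
whisker_adjacent <- function(a, b, whiskers) {
  abs(match(a, whiskers) - match(b, whiskers)) == 1
}

#' Generate a synthetic recording session
#'
#' Draws a [recording_session()] from a [synth_config()], together with the
#' ground truth used by parameter-recovery tests. Identical seeds give
#' identical sessions.
#'
#' @param config A [synth_config()].
#' @return A list with elements `session` (a [recording_session()]) and
#'   `ground_truth` (tibble with one row per neuron: true PW, cell type,
#'   informative flag, expected PW/NW counts, latencies, jitter and
#'   spontaneous rate).
#' @export
generate_session <- function(config = synth_config()) {
  validate_synth_config(config)
  cfg <- config
  seed <- cfg$seed

  n <- cfg$n_neurons
  nw_count <- length(cfg$whiskers)

  # cell types and informative flags cycle deterministically through the
  # target fractions, and per-neuron attributes come from per-neuron
  # sub-streams: appending neurons leaves existing ones untouched
  frac_hits <- function(i, frac) floor(i * frac) > floor((i - 1) * frac)
  cell_type <- character(n)
  informative <- logical(n)
  exc_seen <- 0
  for (i in seq_len(n)) {
    if (frac_hits(i, cfg$inh_fraction)) {
      cell_type[i] <- "INH"
      informative[i] <- TRUE
    } else {
      cell_type[i] <- "EXC"
      exc_seen <- exc_seen + 1
      informative[i] <- frac_hits(exc_seen, cfg$informative_exc_fraction)
    }
  }
  per_neuron <- map(seq_len(n), function(i) {
    with_seed(derive_seed(seed, 1, i), {
      layer <- sample(names(cfg$layer_mix), 1, prob = cfg$layer_mix)
      if (cell_type[i] == "INH") {
        tp <- rnorm(1, 0.20, 0.02)
        asym <- rnorm(1, -0.10, 0.05)
      } else {
        tp <- rnorm(1, 0.41, 0.02)
        asym <- rnorm(1, -0.34, 0.05)
      }
      list(layer = layer, tp = max(tp, 0.05),
           asym = min(max(asym, -1), 1))
    })
  })
  meta <- list(
    layer = map_chr(per_neuron, "layer"),
    informative = informative,
    trough_to_peak_ms = map_dbl(per_neuron, "tp"),
    asymmetry = map_dbl(per_neuron, "asym")
  )

  # principal whisker assignment: INH heterogeneous (round-robin); informative
  # EXC share whiskers[1] when exc_shared_template, else round-robin
  pw <- character(n)
  rr <- function(i) cfg$whiskers[((i - 1) %% nw_count) + 1]
  idx_inh <- which(cell_type == "INH")
  pw[idx_inh] <- rr(seq_along(idx_inh))
  idx_exc <- which(cell_type == "EXC")
  if (length(idx_exc) > 0) {
    if (cfg$exc_shared_template) {
      pw[idx_exc[meta$informative[idx_exc]]] <- cfg$whiskers[1]
      rest <- idx_exc[!meta$informative[idx_exc]]
      pw[rest] <- rr(seq_along(rest))
    } else {
      pw[idx_exc] <- rr(seq_along(idx_exc))
    }
  }

  # --- stimulation protocol ------------------------------------------------
  periodic <- setdiff(cfg$frequencies, "<1")
  block_rows <- list()
  t_cursor <- 10
  block_id <- 0L
  for (w in cfg$whiskers) {
    if ("<1" %in% cfg$frequencies) {
      block_id <- block_id + 1L
      iti <- with_seed(derive_seed(seed, 2, block_id),
                       runif(cfg$trials_low, 5, 30))
      onsets <- t_cursor + cumsum(iti)
      block_rows[[block_id]] <- tibble(block_id = block_id, stimulus_id = w,
                                       frequency_class = "<1",
                                       onset_s = list(onsets))
      t_cursor <- max(onsets) + 10
    }
    for (f in periodic) {
      block_id <- block_id + 1L
      fv <- freq_hz(f)
      onsets <- t_cursor + (seq_len(cfg$trials_high) - 1) / fv
      block_rows[[block_id]] <- tibble(block_id = block_id, stimulus_id = w,
                                       frequency_class = f,
                                       onset_s = list(onsets))
      t_cursor <- max(onsets) + 10
    }
  }
  blocks <- bind_rows(block_rows)
  duration_s <- t_cursor + 10

  # trial-shared multiplicative gain per block (noise-correlation knob)
  gains <- map(seq_len(nrow(blocks)), function(b) {
    n_tr <- length(blocks$onset_s[[b]])
    if (cfg$shared_gain_sd > 0) {
      with_seed(derive_seed(seed, 3, b),
                exp(rnorm(n_tr, 0, cfg$shared_gain_sd)))
    } else {
      rep(1, n_tr)
    }
  })

  # --- spikes --------------------------------------------------------------
  spike_times <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- cell_type[i]
    mu_pw <- cfg$pw_mean_count[[ct]] * cfg$layer_gain[[meta$layer[i]]]
    if (ct == "EXC" && meta$informative[i]) {
      mu_pw <- mu_pw * cfg$informative_exc_gain
    }
    ratio <- if (meta$informative[i]) cfg$nw_count_ratio else 1
    jit <- cfg$jitter_sd_ms[[ct]] / 1000
    evoked <- list()
    for (b in seq_len(nrow(blocks))) {
      stim <- blocks$stimulus_id[b]
      if (stim == pw[i]) {
        mu <- mu_pw
        lat <- cfg$pw_latency_ms / 1000
      } else if (whisker_adjacent(stim, pw[i], cfg$whiskers)) {
        mu <- mu_pw * ratio
        lat <- (cfg$pw_latency_ms + cfg$nw_latency_offset_ms) / 1000
      } else {
        next
      }
      if (mu == 0) next
      onsets <- blocks$onset_s[[b]]
      n_tr <- length(onsets)
      a <- if (is_adapting_frequency(blocks$frequency_class[b])) {
        cfg$adaptation_floor + (1 - cfg$adaptation_floor) *
          exp(-(seq_len(n_tr) - 1) / cfg$adaptation_tau)
      } else {
        rep(1, n_tr)
      }
      evoked[[length(evoked) + 1]] <- with_seed(derive_seed(seed, 4, i, b), {
        counts <- rpois(n_tr, mu * a * gains[[b]])
        if (sum(counts) == 0) {
          numeric(0)
        } else {
          rep(onsets, counts) + lat +
            abs(rnorm(sum(counts), 0, jit))
        }
      })
    }
    spont <- with_seed(derive_seed(seed, 5, i), {
      rate <- cfg$spont_rate_hz[[ct]]
      n_sp <- if (rate > 0) rpois(1, rate * duration_s) else 0L
      if (n_sp > 0) runif(n_sp, 0, duration_s) else numeric(0)
    })
    spike_times[[i]] <- sort(c(unlist(evoked), spont))
  }

  neurons <- tibble(
    neuron_id = seq_len(n),
    layer = meta$layer,
    column = pw,
    cell_type = cell_type,
    trough_to_peak_ms = meta$trough_to_peak_ms,
    asymmetry = meta$asymmetry,
    spike_times = spike_times
  )
  pw_map <- setNames(pw, as.character(seq_len(n)))

  session <- recording_session(neurons, blocks, principal_whisker_map = pw_map,
                               session_id = sprintf("synth-%d", seed),
                               duration_s = duration_s)

  true_mu <- cfg$pw_mean_count[cell_type] * cfg$layer_gain[meta$layer] *
    ifelse(cell_type == "EXC" & meta$informative, cfg$informative_exc_gain, 1)
  ground_truth <- tibble(
    neuron_id = seq_len(n),
    cell_type = cell_type,
    layer = meta$layer,
    true_pw = pw,
    informative = meta$informative,
    pw_mean_count = true_mu,
    nw_mean_count = true_mu *
      ifelse(meta$informative, cfg$nw_count_ratio, 1),
    pw_latency_ms = cfg$pw_latency_ms,
    nw_latency_ms = cfg$pw_latency_ms + cfg$nw_latency_offset_ms,
    jitter_sd_ms = cfg$jitter_sd_ms[cell_type],
    spont_rate_hz = cfg$spont_rate_hz[cell_type]
  )

  list(session = session, ground_truth = ground_truth)
}

#' Summarise the stimulation protocol of a session
#'
#' @param session A [recording_session()].
#' @param exclude_adapted If `TRUE`, report trial counts after dropping the
#'   first 20 trials of blocks at >= 4 Hz (the adaptation-exclusion rule).
#' @return Tibble with one row per block: `block_id`, `stimulus_id`,
#'   `frequency_class`, `n_trials`.
#' @export
protocol_summary <- function(session, exclude_adapted = FALSE) {
  stopifnot(inherits(session, "recording_session"))
  if (nrow(session$blocks) == 0) {
    return(tibble(block_id = integer(), stimulus_id = character(),
                  frequency_class = character(), n_trials = integer()))
  }
  n_trials <- map_int(seq_len(nrow(session$blocks)), function(b) {
    if (exclude_adapted) {
      length(exclude_adapted_trials(session$blocks[b, ]))
    } else {
      length(session$blocks$onset_s[[b]])
    }
  })
  session$blocks |>
    select("block_id", "stimulus_id", "frequency_class") |>
    mutate(n_trials = n_trials)
}
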