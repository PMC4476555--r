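# Internal helpers shared across modules.

FREQ_CLASSES <- c("<1", "1", "2", "4", "7", "10")
LAYERS <- c("L2/3", "L4", "L5A", "L5B/6")
CELL_TYPES <- c("INH", "EXC", "UNCLASSIFIED")

# numeric frequency in Hz; "<1" has no fixed rate (irregular 5-30 s intervals)
freq_hz <- function(frequency_class) {
  out <- suppressWarnings(as.numeric(frequency_class))
  out[frequency_class == "<1"] <- NA_real_
  out
}

# adaptation handling applies at stimulation frequencies >= 4 Hz
is_adapting_frequency <- function(frequency_class) {
  f <- freq_hz(frequency_class)
  !is.na(f) & f >= 4
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# Deterministic 31-bit sub-stream seeds (Lehmer-style mixing) so that adding
# neurons or blocks to a config never perturbs the draws of existing ones.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in idx) {
    h <- (h * 48271 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Total length of the union of half-open intervals [start, end).
interval_union_length <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]
  end <- end[o]
  total <- 0
  cur_s <- start[1]
  cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

# number of sorted values strictly below x (vectorised over x)
n_below <- function(x, sorted_values) {
  findInterval(x, sorted_values, left.open = TRUE)
}

stop_spikeinfo <- function(msg, class = "spikeinfo_error", ...) {
  abort(msg, class = c(class, "spikeinfo_error"), ...)
}
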