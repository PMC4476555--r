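# Trial-by-trial stimulus decoding: PCA dimensionality reduction, linear
# discriminant classification with stratified cross-validation, and
# trial-shuffled surrogates.

#' Flatten a response tensor into a feature matrix
#'
#' @param tensor A [build_responses()] tensor.
#' @param neurons Neuron ids to include (default all).
#' @param space `"pattern"` (trials x neurons*n_bins binary features) or
#'   `"count"` (trials x neurons).
#' @return Numeric matrix with one row per trial.
#' @export
tensor_features <- function(tensor, neurons = NULL,
                            space = c("pattern", "count")) {
  space <- match.arg(space)
  neurons <- neurons %||% tensor$neuron_ids
  cols <- match(neurons, tensor$neuron_ids)
  if (space == "count") {
    out <- tensor$counts[, cols, drop = FALSE]
    storage.mode(out) <- "double"
    return(out)
  }
  n_tr <- nrow(tensor$counts)
  mat <- matrix(0, n_tr, length(cols) * tensor$n_bins)
  for (k in seq_along(cols)) {
    mat[, (k - 1) * tensor$n_bins + seq_len(tensor$n_bins)] <-
      matrix(tensor$patterns[, cols[k], ], ncol = tensor$n_bins)
  }
  mat
}

#' Principal-component reduction of response arrays
#'
#' Mean-centred PCA of the trial x feature response array, keeping the first
#' `n_components` components (components ordered by decreasing explained
#' variance; deterministic sign convention: the largest-magnitude loading of
#' each component is positive). If fewer informative dimensions exist than
#' requested, all are used with a warning.
#'
#' @param x Trials x features matrix.
#' @param n_components Number of components to keep (default 10).
#' @return A `pca_projection`: `scores`, `rotation`, `center`, `sdev`,
#'   `n_components`.
#' @export
reduce_dimensions <- function(x, n_components = 10) {
  x <- as.matrix(x)
  max_comp <- min(dim(x))
  if (n_components > max_comp) {
    warn(sprintf("only %d components available; using all", max_comp))
    n_components <- max_comp
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  structure(
    list(scores = sweep(x, 2, pc$center) %*% rot, rotation = rot,
         center = pc$center, sdev = pc$sdev, n_components = k),
    class = "pca_projection"
  )
}

#' Project new data onto a fitted PCA
#' @param projection A [reduce_dimensions()] fit.
#' @param x New trials x features matrix.
#' @return Score matrix.
#' @export
project_pca <- function(projection, x) {
  sweep(as.matrix(x), 2, projection$center) %*% projection$rotation
}

# ---- Gaussian LDA with pooled shrinkage covariance ------------------------

# Ledoit-Wolf shrinkage intensity toward the scaled identity target, from
# within-class-centred observations
lw_lambda <- function(xc, S) {
  n <- nrow(xc)
  p <- ncol(xc)
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, p))^2)
  if (d2 < 1e-12) return(0)
  b2_sum <- 0
  for (t in seq_len(n)) {
    b2_sum <- b2_sum + sum((tcrossprod(xc[t, ]) - S)^2)
  }
  b2 <- min(b2_sum / n^2, d2)
  b2 / d2
}

fit_lda <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  n <- nrow(x)
  p <- ncol(x)
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(x[y == cl, , drop = FALSE])
  }))
  priors <- as.numeric(table(y)) / n
  xc <- x - means[as.integer(y), , drop = FALSE]
  S <- crossprod(xc) / max(n - length(classes), 1)
  lambda <- if (identical(shrinkage, "auto")) lw_lambda(xc, S)
            else as.numeric(shrinkage)
  m <- mean(diag(S))
  S_shr <- (1 - lambda) * S + diag(lambda * m + 1e-10, p)
  Sinv <- solve(S_shr)
  W <- Sinv %*% t(means)
  b <- -0.5 * colSums(t(means) * W) + log(priors)
  structure(list(W = W, b = b, classes = classes, lambda = lambda),
            class = "lda_model")
}

predict_lda <- function(model, x) {
  scores <- as.matrix(x) %*% model$W +
    matrix(model$b, nrow(as.matrix(x)), length(model$b), byrow = TRUE)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated linear discriminant decoding
#'
#' Stratified `n_folds`-way cross-validation (default four-way: 75% of
#' trials train each discriminant, 25% test it) of a linear discriminant
#' classifier with pooled, shrinkage-regularised covariance. Optionally the
#' features are first reduced to `n_components` principal components; by
#' default the projection is fitted on the training folds only
#' (`pca_per_fold = TRUE`), avoiding test-set leakage; set it to `FALSE` to
#' fit the projection once on the whole array.
#'
#' @param features Trials x features matrix (e.g. [tensor_features()]).
#' @param labels Stimulus class per trial (>= `n_folds` trials per class).
#' @param n_folds Number of folds (default 4).
#' @param seed Seed for the fold assignment.
#' @param n_components If non-`NULL`, reduce to this many principal
#'   components before classification.
#' @param pca_per_fold Fit the PCA on training folds only (default `TRUE`).
#' @param shrinkage `"auto"` (analytic Ledoit-Wolf intensity) or a number in
#'   \[0, 1\].
#' @return A `decoding_result`: `performance` (pooled percent correct),
#'   `fold_performance`, `confusion` (true x decoded counts),
#'   `transmitted_bits`, `n_components_used`, `n_train_per_fold`,
#'   `n_test_per_fold`, `chance_level`, `shuffled`, `seed`.
#' @export
lda_crossval <- function(features, labels, n_folds = 4, seed = NULL,
                         n_components = NULL, pca_per_fold = TRUE,
                         shrinkage = "auto") {
  features <- as.matrix(features)
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- factor(labels[keep])
  classes <- levels(labels)
  tab <- table(labels)
  if (length(classes) < 2) stop_spikeinfo("need >= 2 stimulus classes")
  if (any(tab < n_folds)) {
    stop_spikeinfo(sprintf("every class needs >= %d trials for %d-fold CV",
                           n_folds, n_folds))
  }

  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })

  glob_proj <- NULL
  if (!is.null(n_components) && !pca_per_fold) {
    glob_proj <- reduce_dimensions(features, n_components)
  }

  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, decoded = classes))
  fold_perf <- numeric(n_folds)
  n_train <- integer(n_folds)
  n_test <- integer(n_folds)
  n_comp_used <- if (is.null(n_components)) ncol(features) else n_components

  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- fold == f
    if (length(unique(labels[tr])) < length(classes)) {
      stop_spikeinfo(sprintf("class missing from training folds at fold %d", f))
    }
    x_tr <- features[tr, , drop = FALSE]
    x_te <- features[te, , drop = FALSE]
    if (!is.null(glob_proj)) {
      x_tr <- project_pca(glob_proj, x_tr)
      x_te <- project_pca(glob_proj, x_te)
      n_comp_used <- glob_proj$n_components
    } else if (!is.null(n_components)) {
      proj <- reduce_dimensions(x_tr, n_components)
      x_tr <- proj$scores
      x_te <- project_pca(proj, x_te)
      n_comp_used <- proj$n_components
    }
    model <- fit_lda(x_tr, labels[tr], shrinkage)
    pred <- predict_lda(model, x_te)
    truth <- as.character(labels[te])
    for (k in seq_along(pred)) {
      confusion[truth[k], pred[k]] <- confusion[truth[k], pred[k]] + 1L
    }
    fold_perf[f] <- 100 * mean(pred == truth)
    n_train[f] <- sum(tr)
    n_test[f] <- sum(te)
  }

  structure(
    list(performance = 100 * sum(diag(confusion)) / sum(confusion),
         fold_performance = fold_perf,
         confusion = confusion,
         transmitted_bits = transmitted_info(confusion),
         n_components_used = n_comp_used,
         n_train_per_fold = n_train,
         n_test_per_fold = n_test,
         chance_level = 100 / length(classes),
         shuffled = FALSE, seed = seed),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %.1f%% correct (chance %.1f%%), %.4f transmitted bits%s\n",
    x$performance, x$chance_level, x$transmitted_bits,
    if (isTRUE(x$shuffled)) " [trial-shuffled input]" else ""))
  invisible(x)
}

#' Trial-shuffled surrogate responses
#'
#' Within each stimulus class, every neuron's per-trial responses (count and
#' pattern together) are permuted with an independent permutation per
#' neuron. Per-class response multisets of each neuron are preserved exactly
#' (signal correlations kept); the trial-by-trial pairing across neurons is
#' destroyed (noise correlations removed).
#'
#' @param tensor A [build_responses()] tensor.
#' @param seed Seed for the permutations.
#' @param labels Stimulus class per trial defining the within-class
#'   permutation groups (defaults to the stimulus ids; pass frequency-class
#'   labels for frequency-coding analyses).
#' @return A `response_tensor` flagged `shuffled = TRUE`.
#' @export
shuffle_trials <- function(tensor, seed = NULL, labels = NULL) {
  stopifnot(inherits(tensor, "response_tensor"))
  out <- tensor
  labels <- labels %||% tensor$trial_info$stimulus_id
  with_seed(seed, {
    for (cl in unique(labels)) {
      tr <- which(labels == cl)
      if (length(tr) < 2) next
      for (j in seq_along(tensor$neuron_ids)) {
        perm <- sample(length(tr))
        out$counts[tr, j] <- tensor$counts[tr[perm], j]
        out$patterns[tr, j, ] <- tensor$patterns[tr[perm], j, ]
      }
    }
  })
  out$shuffled <- TRUE
  out
}

#' Across-trial variability of the ensemble response
#'
#' For each trial the population response level is the mean spike count per
#' neuron; the variability is the SD of this level across trials of the same
#' stimulus class, averaged over classes weighted by trial counts. Trial
#' shuffling homogenises the response level across trials, so shared-gain
#' fluctuations lower this measure when removed.
#'
#' @param tensor A [build_responses()] tensor, or a counts matrix.
#' @param labels Stimulus class per trial (defaults to the tensor's
#'   stimulus ids).
#' @return SD of the per-trial population spike count (spikes).
#' @export
ensemble_variability <- function(tensor, labels = NULL) {
  if (inherits(tensor, "response_tensor")) {
    counts <- tensor$counts
    labels <- labels %||% tensor$trial_info$stimulus_id
  } else {
    counts <- as.matrix(tensor)
    labels <- labels %||% rep("all", nrow(counts))
  }
  if (nrow(counts) < 2) stop_spikeinfo("need >= 2 trials")
  level <- rowMeans(counts)
  sds <- vapply(unique(labels), function(cl) {
    v <- level[labels == cl]
    if (length(v) < 2) NA_real_ else sd(v)
  }, numeric(1))
  w <- as.numeric(table(factor(labels, unique(labels))))
  ok <- !is.na(sds)
  sum(sds[ok] * w[ok]) / sum(w[ok])
}

#' Shuffle gain versus variability decrease
#'
#' Relates the relative increase in decoding performance obtained after
#' trial-shuffling to the relative decrease in ensemble response
#' variability, across (group, condition) points. A positive Pearson
#' correlation indicates that shuffling helps most where shared trial-to-
#' trial gain fluctuations inflate response variability.
#'
#' @param points Tibble with columns `performance`,
#'   `performance_shuffled`, `sd_count`, `sd_count_shuffled` (one row per
#'   group/condition; extra columns are carried through).
#' @param n_perm Permutations for the two-sided p-value (default 2000).
#' @param seed Seed for the permutation test.
#' @return A `shuffle_gain_analysis`: the augmented `table` (with
#'   `perf_gain` and `var_decrease`), `r` and `p_value`.
#' @export
shuffle_gain_analysis <- function(points, n_perm = 2000, seed = NULL) {
  points <- as_tibble(points)
  if (nrow(points) < 3) stop_spikeinfo("need >= 3 points")
  points <- points |>
    mutate(
      perf_gain = (.data$performance_shuffled - .data$performance) /
        .data$performance,
      var_decrease = (.data$sd_count - .data$sd_count_shuffled) /
        .data$sd_count
    )
  x <- points$perf_gain
  y <- points$var_decrease
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_
    p <- NA_real_
  } else {
    r <- cor(x, y)
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(cor(x, sample(y))) >= abs(r) - 1e-12
      }, logical(1)))
    })
    p <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(table = points, r = r, p_value = p),
            class = "shuffle_gain_analysis")
}

#' @export
print.shuffle_gain_analysis <- function(x, ...) {
  cat(sprintf("<shuffle_gain_analysis> R = %.3f (p = %.4g) over %d points\n",
              x$r, x$p_value, nrow(x$table)))
  invisible(x)
}
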