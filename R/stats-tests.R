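# Statistical testing layer: normality-gated two-sample tests,
# permutation-based two-way ANOVA, and FDR correction.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardised skewness and kurtosis statistics into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-square with 2 df. Requires n >= 8.
#'
#' @param x Numeric sample.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop_spikeinfo("D'Agostino-Pearson test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                z_skew = NA_real_, z_kurt = NA_real_))
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  g2 <- m4 / m2^2
  e_g2 <- 3 * (n - 1) / (n + 1)
  v_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - e_g2) / sqrt(v_g2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  inner <- (1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4)))
  z2 <- ((1 - 2 / (9 * A)) - sign(inner) * abs(inner)^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

new_test_result <- function(statistic, p_value, test_name, n, paired,
                            degenerate = FALSE) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         test_name = test_name, n = n, paired = paired,
         degenerate = degenerate),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Each sample is first tested for normality (D'Agostino-Pearson). When both
#' samples are normal AND both have n >= 20, a parametric t-test
#' (independent or paired) is used; otherwise the Mann-Whitney U test
#' (independent) or the paired Wilcoxon signed-rank test. Samples below the
#' size gate always take the nonparametric branch. Identical zero-variance
#' samples short-circuit to p = 1 with a degenerate flag.
#'
#' @param x,y Numeric samples (>= 3 observations each).
#' @param paired Paired design (requires equal lengths).
#' @return A `test_result`.
#' @export
gated_two_sample_test <- function(x, y, paired = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3) {
    stop_spikeinfo("each sample needs >= 3 observations")
  }
  if (paired && length(x) != length(y)) {
    stop_spikeinfo("paired samples must have equal length")
  }
  if ((paired && all(x == y)) ||
      (sd(x) == 0 && sd(y) == 0 && x[1] == y[1])) {
    return(new_test_result(NA_real_, 1, "degenerate (identical samples)",
                           c(length(x), length(y)), paired,
                           degenerate = TRUE))
  }
  is_normal <- function(v) {
    if (length(v) < 8 || sd(v) == 0) return(FALSE)
    dagostino_pearson(v)$p_value > 0.05
  }
  use_parametric <- is_normal(x) && is_normal(y) &&
    length(x) >= 20 && length(y) >= 20
  if (use_parametric) {
    ht <- t.test(x, y, paired = paired)
    name <- if (paired) "paired t-test" else "independent t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired))
    name <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
  new_test_result(ht$statistic, ht$p.value, name,
                  c(length(x), length(y)), paired)
}

#' Permutation-based two-way ANOVA
#'
#' F statistics from the sequential two-way factorial decomposition
#' (main effect A, main effect B, interaction), with p-values obtained by
#' unrestricted permutation of the observations:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. The F statistics are
#' invariant to affine transforms of the values, so the p-values are too.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (>= 2 levels each; no empty cells).
#' @param n_perm Number of permutations (>= 1; default 1000).
#' @param seed Seed for the permutations.
#' @return Tibble: `term` (`"factor_a"`, `"factor_b"`, `"interaction"`),
#'   `df`, `statistic` (F), `p_value`.
#' @export
permutation_anova <- function(values, factor_a, factor_b, n_perm = 1000,
                              seed = NULL) {
  if (n_perm < 1) stop_spikeinfo("n_perm must be >= 1")
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop_spikeinfo("both factors need >= 2 levels")
  }
  if (any(table(a, b) == 0)) {
    stop_spikeinfo("design has empty cells")
  }
  y <- as.numeric(values)
  n <- length(y)
  stopifnot(length(a) == n, length(b) == n)

  mm <- stats::model.matrix(~ a * b)
  assign <- attr(mm, "assign")
  qr_mm <- qr(mm)
  Q <- qr.Q(qr_mm)
  df_res <- n - ncol(mm)
  if (df_res < 1) stop_spikeinfo("no residual degrees of freedom")

  perm_idx <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  Y <- cbind(y, matrix(y[perm_idx], nrow = n))
  B2 <- (t(Q) %*% Y)^2

  f_stats <- function(col) {
    ss_tot <- sum(Y[, col]^2)
    ss_terms <- vapply(1:3, function(g) sum(B2[assign == g, col]), numeric(1))
    ss_res <- ss_tot - sum(B2[, col])
    df_terms <- vapply(1:3, function(g) sum(assign == g), numeric(1))
    (ss_terms / df_terms) / (ss_res / df_res)
  }
  Fs <- vapply(seq_len(ncol(Y)), f_stats, numeric(3))
  f_obs <- Fs[, 1]
  p <- vapply(1:3, function(g) {
    (1 + sum(Fs[g, -1] >= f_obs[g] - 1e-12)) / (1 + n_perm)
  }, numeric(1))
  tibble(
    term = c("factor_a", "factor_b", "interaction"),
    df = vapply(1:3, function(g) sum(assign == g), numeric(1)),
    statistic = f_obs,
    p_value = p
  )
}

#' False discovery rate correction
#'
#' Benjamini-Hochberg step-up adjusted p-values (the default posthoc
#' correction after the permutation ANOVA); Benjamini-Yekutieli available
#' for dependent tests.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted q-values, same length.
#' @export
fdr_correct <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_spikeinfo("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = method)
}
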