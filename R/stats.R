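# Repeated-measures inference across the seven volume timestamps and
# correlation analysis.

as_rm_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || anyNA(m))
    retorg_error("parameter", "measurement table must be numeric with no missing cells")
  if (nrow(m) < 2L || ncol(m) < 2L)
    retorg_error("inference", "need >= 2 subjects and >= 2 timestamps")
  m
}

#' One-way repeated-measures ANOVA
#'
#' Univariate within-subject ANOVA of a subjects-by-timestamps table via the
#' sums-of-squares decomposition SS_total = SS_subject + SS_time + SS_error,
#' with `F = MS_time / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. No sphericity correction is applied to the primary p-value; the
#' Greenhouse-Geisser epsilon is reported alongside as a diagnostic.
#'
#' @param table Numeric matrix or data.frame, subjects in rows, timestamps
#'   in columns, no missing cells.
#' @return An `anova_result`: F, degrees of freedom, p-value, sums of
#'   squares, per-timestamp means with 95% confidence intervals, and the
#'   Greenhouse-Geisser epsilon.
#' @export
rm_anova <- function(table) {
  m <- as_rm_table(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_time
  df_t <- k - 1L; df_e <- (k - 1L) * (n - 1L)
  if (ss_err <= .Machine$double.eps * ss_tot) {
    if (ss_time <= .Machine$double.eps * max(ss_tot, 1)) {
      f <- 0; p <- 1
    } else {
      retorg_error("degenerate_variance",
                   "zero within-subject error variance; F undefined")
    }
  } else {
    f <- (ss_time / df_t) / (ss_err / df_e)
    p <- stats::pf(f, df_t, df_e, lower.tail = FALSE)
  }
  cm <- colMeans(m)
  cs <- apply(m, 2L, stats::sd)
  hw <- stats::qt(0.975, n - 1L) * cs / sqrt(n)

  # Greenhouse-Geisser epsilon from the column covariance matrix
  S <- stats::cov(m)
  sbar <- mean(S)
  num <- (k * (mean(diag(S)) - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  gg <- if (den > 0) num / den else NA_real_

  structure(list(F = f, df = c(effect = df_t, error = df_e), p.value = p,
                 ss = c(subject = ss_subj, time = ss_time, error = ss_err,
                        total = ss_tot),
                 means = cm, ci_lower = cm - hw, ci_upper = cm + hw,
                 sd = cs, n_subjects = n, gg_epsilon = gg),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g (GG eps = %.3f)\n",
              x$df[1L], x$df[2L], x$F, x$p.value, x$gg_epsilon))
  invisible(x)
}

#' Bonferroni post-hoc tests against the baseline
#'
#' Paired two-sided t-tests of each dark-adaptation timestamp against the
#' light-adapted baseline column, with Bonferroni adjustment over the family
#' of baseline comparisons (`k - 1` for a `k`-timestamp design; 6 here), and
#' the earliest timestamp whose adjusted p falls below `alpha`. The
#' all-pairs family is available behind `family = "all_pairs"`.
#'
#' @param table Subjects-by-timestamps matrix or data.frame.
#' @param baseline Baseline column index (default 1).
#' @param alpha Significance level (default 0.05).
#' @param family `"baseline"` (default) or `"all_pairs"`.
#' @param timestamps Optional timestamp labels (defaults to column names or
#'   indices).
#' @return A `posthoc_result` with raw and adjusted p-values, the Bonferroni
#'   factor, and `earliest_significant` (a timestamp label, or `NA`).
#' @export
bonferroni_vs_baseline <- function(table, baseline = 1L, alpha = 0.05,
                                   family = c("baseline", "all_pairs"),
                                   timestamps = NULL) {
  m <- as_rm_table(table)
  family <- match.arg(family)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) retorg_error("inference", "need >= 2 subjects for paired tests")
  ts <- timestamps %||% colnames(m) %||% as.character(seq_len(k))
  others <- setdiff(seq_len(k), baseline)
  raw <- vapply(others, function(j)
    stats::t.test(m[, j], m[, baseline], paired = TRUE)$p.value, numeric(1))
  factor <- if (family == "baseline") k - 1L else k * (k - 1L) / 2L
  adj <- pmin(1, raw * factor)
  sig <- which(adj < alpha)
  structure(list(comparison = ts[others], p.raw = raw, p.adjusted = adj,
                 factor = factor, alpha = alpha,
                 earliest_significant = if (length(sig)) ts[others][min(sig)]
                 else NA_character_),
            class = "posthoc_result")
}

#' Pearson correlation
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p.value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    retorg_error("parameter", "need equal-length series of >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    retorg_error("degenerate", "zero variance in a correlation input")
  r <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p.value = p, n = n)
}
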