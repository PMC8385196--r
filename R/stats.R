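#' Adaptive two-group comparison
#'
#' Implements the gated test-selection flow used for all two-group
#' comparisons: each group is first checked for normality (Shapiro-Wilk); if
#' either group is non-normal at `alpha` the two-sided Mann-Whitney U test is
#' used. Otherwise homogeneity of variance is checked (Levene's test,
#' mean-centred); if it fails, the separate-variance (Welch) t-test is used,
#' else the pooled-variance t-test. All gate p-values are returned so the
#' routing is auditable.
#'
#' A zero-variance group makes Shapiro-Wilk undefined; such data are routed
#' to Mann-Whitney with a warning. The Mann-Whitney p-value is computed by
#' exact enumeration when both groups have n < 8 and there are no ties, and
#' by the tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param x,y numeric vectors (n >= 3 each) or lists with `$values` and
#'   `$label`.
#' @param alpha significance level for the normality and variance gates
#'   (default 0.05).
#' @return object of class `test_result`: `branch` (`"pooled_t"`,
#'   `"welch_t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `normality_p` (length 2), `levene_p` (`NA` unless that gate was
#'   reached), `alpha`, group summaries (`mean_sem` per group).
#' @export
#' @examples
#' a <- c(5.1, 4.8, 5.4, 5.0, 5.2)
#' b <- c(4.2, 4.5, 4.1, 4.4, 4.3)
#' compare_groups(a, b)$branch
compare_groups <- function(x, y, alpha = 0.05) {
  gx <- as_group(x, "x"); gy <- as_group(y, "y")
  for (g in list(gx, gy)) {
    if (length(g$values) < 3)
      stop_motomap("each group needs n >= 3 for the normality gate")
    if (!all(is.finite(g$values)))
      stop_motomap("group values must be finite")
  }
  degenerate <- sd(gx$values) == 0 || sd(gy$values) == 0
  if (degenerate) {
    warning("zero-variance group: Shapiro-Wilk undefined, ",
            "using Mann-Whitney", call. = FALSE)
    norm_p <- c(NA_real_, NA_real_)
  } else {
    norm_p <- c(shapiro.test(gx$values)$p.value,
                shapiro.test(gy$values)$p.value)
  }
  levene_p <- NA_real_
  if (degenerate || any(norm_p < alpha)) {
    branch <- "mann_whitney"
    ht <- mann_whitney_u(gx$values, gy$values)
  } else {
    levene_p <- levene_p_value(gx$values, gy$values)
    if (levene_p < alpha) {
      branch <- "welch_t"
      ht <- t.test(gx$values, gy$values, var.equal = FALSE)
    } else {
      branch <- "pooled_t"
      ht <- t.test(gx$values, gy$values, var.equal = TRUE)
    }
  }
  structure(list(branch = branch,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 normality_p = norm_p, levene_p = levene_p, alpha = alpha,
                 groups = list(x = list(label = gx$label,
                                        summary = mean_sem(gx$values)),
                               y = list(label = gy$label,
                                        summary = mean_sem(gy$values)))),
            class = "test_result")
}

as_group <- function(g, default_label) {
  if (is.list(g) && !is.null(g$values))
    list(values = as.numeric(g$values),
         label = if (is.null(g$label)) default_label else g$label)
  else list(values = as.numeric(g), label = default_label)
}

levene_p_value <- function(x, y) {
  values <- c(x, y)
  group <- factor(rep(c("x", "y"), c(length(x), length(y))))
  out <- car::leveneTest(values, group, center = mean)
  out[["Pr(>F)"]][1]
}

mann_whitney_u <- function(x, y) {
  exact <- length(x) < 8 && length(y) < 8 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> branch %s: statistic %.4g, p = %.4g\n",
              x$branch, x$statistic, x$p_value))
  cat(sprintf("  gates: Shapiro-Wilk p = %s; Levene p = %s (alpha %.3g)\n",
              paste(signif(x$normality_p, 3), collapse = ", "),
              signif(x$levene_p, 3), x$alpha))
  invisible(x)
}

#' Percent improvement of a value over a reference
#'
#' `100 * (value_new - value_ref) / value_ref`, rounded to two decimals with
#' half away from zero, the convention used for reported percentages.
#'
#' @param value_new,value_ref scalars; `value_ref` must be positive.
#' @return percent, rounded to 2 decimals.
#' @export
#' @examples
#' percent_improvement(183, 109)  # 67.89
percent_improvement <- function(value_new, value_ref) {
  if (!is.finite(value_ref) || value_ref <= 0)
    stop_motomap("`value_ref` must be positive")
  round_half_away(100 * (value_new - value_ref) / value_ref, 2L)
}

round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean and standard error of the mean
#'
#' @param sample numeric vector, n >= 2.
#' @return named numeric `c(mean =, sem =)` with `sem = sd / sqrt(n)` (sample
#'   SD, n - 1 denominator).
#' @export
mean_sem <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 2) stop_motomap("need n >= 2 for a SEM")
  c(mean = mean(sample), sem = sd(sample) / sqrt(length(sample)))
}
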