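# Group summaries and rank-based comparisons: mean +/- SD, 10-90 percentile
# box summaries, Kruskal-Wallis (one-way ANOVA on ranks) with Dunn's
# multiple-comparisons test, and a parametric ANOVA/Tukey alternative.

#' Summary statistics of one measurement group
#'
#' Mean, n-1 sample standard deviation, and the 10/25/50/75/90 percentiles
#' (linear interpolation between closest ranks) — the summaries used for
#' 10-90 percentile boxplots.
#'
#' @param values Numeric vector, finite, n >= 1.
#' @return Named list: `n`, `mean`, `sd` (NA for n = 1), `p10`, `p25`, `p50`,
#'   `p75`, `p90`.
#' @examples
#' summarize_sample(1:100)$p10 # 10.9
#' @export
summarize_sample <- function(values) {
  if (!length(values)) stop("empty sample: no values to summarize")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                       names = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5])
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' One-way ANOVA on ranks: the tie-corrected Kruskal-Wallis H statistic with
#' a chi-square global p-value, followed by Dunn's pairwise z tests
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p-values
#' adjusted by Bonferroni (default) or Holm.
#'
#' @param values Numeric vector of all measurements.
#' @param groups Factor/character vector of group labels, same length.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return A `comparison_result`: list with `H`, `df`, `p_global`, `groups`
#'   (per-group n and mean rank) and `pairwise` (data.frame `group_i`,
#'   `group_j`, `z`, `p`, `p_adjusted`).
#' @examples
#' set.seed(1)
#' kruskal_dunn(c(rnorm(8), rnorm(8, 2)), rep(c("a", "b"), each = 8))
#' @export
kruskal_dunn <- function(values, groups, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(groups))
  if (!all(is.finite(values))) stop("values must be finite")
  groups <- factor(groups)
  n_i <- table(groups)
  if (any(n_i == 0)) stop("every group needs at least one observation")
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  N <- length(values)
  if (N < k + 1) stop("need total n >= k + 1")
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  H <- (12 / (N * (N + 1))) * sum(as.numeric(n_i) * (Rbar - (N + 1) / 2)^2)
  corr <- 1 - tie_sum / (N^3 - N)
  H <- if (corr > 0) H / corr else NA_real_
  p_global <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)

  Tterm <- tie_sum / (12 * (N - 1))
  sig2 <- N * (N + 1) / 12 - Tterm
  pairs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(sig2 * (1 / n_i[[i]] + 1 / n_i[[j]]))
    z[m] <- (Rbar[[i]] - Rbar[[j]]) / se
    p[m] <- 2 * stats::pnorm(-abs(z[m]))
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  structure(list(
    H = H, df = k - 1, p_global = p_global,
    groups = data.frame(group = levels(groups), n = as.integer(n_i),
                        mean_rank = as.numeric(Rbar)),
    pairwise = data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                          z = z, p = p, p_adjusted = p_adj),
    adjust = adjust
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g\n",
              x$H, x$df, x$p_global))
  cat(sprintf("Dunn pairwise (two-sided, %s-adjusted):\n", x$adjust))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parametric one-way ANOVA with Tukey HSD
#'
#' The parametric alternative to [kruskal_dunn()] (used for approximately
#' normal measurements such as spread areas); wraps `stats::aov` and
#' `stats::TukeyHSD`.
#'
#' @param values Numeric vector of all measurements.
#' @param groups Group labels, same length.
#' @return List with `F`, `df`, `p_global` and `pairwise` (data.frame
#'   `comparison`, `diff`, `p_adjusted`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1], df = s[["Df"]],
       p_global = s[["Pr(>F)"]][1],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             p_adjusted = tk[, "p adj"],
                             row.names = NULL))
}
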