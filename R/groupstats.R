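## Group-comparison statistics: Shapiro-Wilk normality gating, two-group
## Mann-Whitney (t test fallback when both groups look normal), multi-group
## Kruskal-Wallis with Dunn's post hoc, Pearson correlation.

#' Two-group comparison with normality gating
#'
#' Each group is first assessed with a Shapiro-Wilk test; a group is
#' considered normally distributed when its p-value is > 0.05. If either
#' group fails (or is too small to test, n < 3, which forces the
#' nonparametric branch with a warning), a two-sided Mann-Whitney test is
#' used - exact when both groups have n <= 20 and the data are tie-free,
#' otherwise the normal approximation with tie and continuity correction.
#' When both groups pass, a two-sided Welch t test is used and flagged as
#' the parametric branch.
#'
#' @param values numeric vector.
#' @param groups parallel labels with exactly two levels.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A list: `test`, `statistic`, `p_value`, `stars`, `group_sizes`,
#'   `normality_p`, `parametric` (logical), `alpha`.
#' @examples
#' compareTwoGroups(c(1, 2, 3, 4, 5, 6),
#'                  rep(c("a", "b"), each = 3))$p_value  # 0.1 (exact)
#' @export
compareTwoGroups <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  v1 <- values[g == levels(g)[1L]]
  v2 <- values[g == levels(g)[2L]]
  if (!length(v1) || !length(v2)) stop("both groups must be nonempty")

  normP <- c(NA_real_, NA_real_)
  if (length(v1) < 3L || length(v2) < 3L) {
    warning("a group has n < 3; normality gate skipped, nonparametric ",
            "branch forced")
    normal <- FALSE
  } else {
    normP <- c(stats::shapiro.test(v1)$p.value,
               stats::shapiro.test(v2)$p.value)
    ## the gate is only trusted when it could ever reject: at n = 3 the
    ## Shapiro-Wilk p cannot fall below conventional alpha, so tiny groups
    ## always take the rank-based branch
    normal <- length(v1) >= 4L && length(v2) >= 4L && all(normP > 0.05)
  }
  names(normP) <- levels(g)

  if (normal) {
    t <- stats::t.test(v1, v2, alternative = "two.sided")
    res <- list(test = "Welch t test (both groups normal)",
                statistic = unname(t$statistic), p_value = t$p.value,
                parametric = TRUE)
  } else {
    ties <- anyDuplicated(c(v1, v2)) > 0L
    exact <- length(v1) <= 20L && length(v2) <= 20L && !ties
    w <- suppressWarnings(
      stats::wilcox.test(v1, v2, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    res <- list(test = if (exact) "Mann-Whitney (exact)"
                else "Mann-Whitney (normal approximation)",
                statistic = unname(w$statistic), p_value = w$p.value,
                parametric = FALSE)
  }
  c(res, list(stars = .pStars(res$p_value),
              group_sizes = stats::setNames(c(length(v1), length(v2)),
                                            levels(g)),
              normality_p = normP, alpha = alpha))
}

## Tie-corrected Dunn z statistics for all pairwise comparisons after a
## Kruskal-Wallis test. No installed package provides Dunn's test, so the
## rank algebra is implemented directly.
.dunnTest <- function(values, g, method = "bonferroni") {
  N <- length(values)
  r <- rank(values)
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / (12 * (N - 1))
  meanRank <- tapply(r, g, mean)
  n <- table(g)
  pairs <- utils::combn(levels(g), 2L)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                 (1 / n[[p[1L]]] + 1 / n[[p[2L]]]))
    (meanRank[[p[1L]]] - meanRank[[p[2L]]]) / se
  })
  praw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_value = praw,
             p_adjusted = pmin(1, stats::p.adjust(praw, method = method)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multi-group comparison: Kruskal-Wallis with Dunn's post hoc
#'
#' A tie-corrected Kruskal-Wallis test across all groups, followed by
#' Dunn's z test for every pair of groups with multiplicity adjustment over
#' all pairs (Bonferroni by default, Prism-compatible; Holm available).
#' Per-pair significance stars use the conventional tiers
#' (`*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001).
#'
#' @param values numeric vector.
#' @param groups parallel labels with at least three nonempty levels.
#' @param alpha significance level recorded in the result.
#' @param pAdjust `"bonferroni"` (default) or `"holm"`.
#' @return A list: `test`, `statistic` (KW H), `df`, `p_value`, `pairwise`
#'   (data.frame with `z`, raw and adjusted p, `stars`), `group_sizes`,
#'   `alpha`.
#' @export
compareMultiGroups <- function(values, groups, alpha = 0.05,
                               pAdjust = c("bonferroni", "holm")) {
  pAdjust <- match.arg(pAdjust)
  g <- factor(groups)
  if (nlevels(g) < 3L) stop("at least three groups required")
  if (any(table(g) == 0L)) stop("every group must be nonempty")
  kw <- stats::kruskal.test(values, g)
  pw <- .dunnTest(values, g, method = pAdjust)
  pw$stars <- .pStars(pw$p_adjusted)
  list(test = "Kruskal-Wallis + Dunn post hoc",
       statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = pw,
       group_sizes = stats::setNames(as.integer(table(g)), levels(g)),
       alpha = alpha)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation and its two-sided p-value from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param x,y equal-length finite numeric vectors, n >= 3, each with
#'   nonzero variance.
#' @return A list: `r`, `p_value`, `n`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
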