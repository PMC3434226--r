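## Group-comparison statistics: Kruskal-Wallis omnibus test, Dunn's
## pairwise post test with Bonferroni adjustment, and percentile-bootstrap
## confidence intervals for cluster means. Pixels within a cluster are
## treated as independent observations; under spatial autocorrelation this
## inflates significance (documented limitation).

#' Kruskal-Wallis rank-sum test on named groups
#'
#' Tie-corrected H with a chi-square approximation on k-1 degrees of
#' freedom (delegates to [stats::kruskal.test()]). The degenerate case of
#' all observations identical returns `H = 0`, `p = 1` by convention.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each
#'   non-empty, total n >= 3).
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(values) < 3) rr_error("need total n >= 3", "rr_stats_error")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    rr_error("need a list of >= 2 groups", "rr_stats_error")
  if (any(lengths(groups) == 0))
    rr_error("every group needs at least one value", "rr_stats_error")
  invisible(groups)
}

#' Dunn's multiple-comparison post test
#'
#' Pairwise z statistics on mean ranks with pooled rank variance and tie
#' correction:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' p-values are two-sided and adjusted over all k(k-1)/2 pairs
#' (Bonferroni by default).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param adjustment p-adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @param alpha Significance level for the `significant` flags
#'   (default 0.05).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`,
#'   `significant`.
#' @export
dunn_posthoc <- function(groups, adjustment = "bonferroni", alpha = 0.05) {
  check_groups(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)  # mid-ranks for ties
  idx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(v * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = adjustment)
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             z = as.numeric(z), p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Percentile-bootstrap confidence interval of the mean
#'
#' Seeded, vectorised percentile bootstrap. A constant sample yields a
#' zero-width interval; `n = 1` returns the degenerate interval
#' `[value, value]` with `degenerate = TRUE`.
#'
#' @param values Numeric vector (n >= 1).
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param n_resamples Bootstrap resamples (default 10000).
#' @param seed Random seed.
#' @return List with `mean`, `lo`, `hi`, `degenerate`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_resamples = 10000, seed = 1) {
  if (!length(values)) rr_error("need n >= 1", "rr_stats_error")
  if (level <= 0 || level >= 1) rr_error("level must be in (0,1)", "rr_stats_error")
  m <- mean(values)
  if (length(values) == 1L)
    return(list(mean = m, lo = m, hi = m, degenerate = TRUE))
  set.seed(seed)
  n <- length(values)
  draws <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
  means <- colMeans(matrix(values[draws], nrow = n))
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(mean = m, lo = qs[1], hi = qs[2], degenerate = FALSE)
}

#' Omnibus + post-hoc report for per-cluster samples
#'
#' Convenience wrapper producing the statistics reported alongside cluster
#' ratio tables: Kruskal-Wallis omnibus and Dunn's pairwise comparisons.
#'
#' @inheritParams dunn_posthoc
#' @return List of class `stats_report` with `omnibus` (list `H`, `p`,
#'   `df`) and `pairwise` (the [dunn_posthoc()] table).
#' @export
stats_report <- function(groups, adjustment = "bonferroni", alpha = 0.05) {
  structure(list(omnibus = kruskal_wallis(groups),
                 pairwise = dunn_posthoc(groups, adjustment, alpha),
                 alpha = alpha),
            class = "stats_report")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a recovered clustering and reference
#' labels; pairs with `NA` in either labeling are dropped. Used for
#' phantom cluster-recovery checks (cross-checked against
#' `mclust::adjustedRandIndex` in the test suite).
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI (1 = identical partitions up to renaming).
#' @export
adjusted_rand_index <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  exp_ <- si * sj / ch2(n)
  max_ <- (si + sj) / 2
  if (max_ == exp_) return(1)
  (sij - exp_) / (max_ - exp_)
}
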