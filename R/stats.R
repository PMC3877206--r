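# Rank-based group statistics: two-tailed Mann-Whitney (exact for small,
# tie-free samples), Kruskal-Wallis with tie correction, Dunn's pairwise
# post tests with family-wise (Bonferroni) adjustment, and the conventional
# significance stars at 0.05 / 0.01 / 0.001.

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Exact two-sided Mann-Whitney p-value by enumeration
#'
#' Independent small-sample oracle: enumerates all `choose(nA+nB, nA)`
#' assignments of the pooled midranks to group A and computes the two-sided
#' tail probability `2 * min(P(U <= u), P(U >= u))`, capped at 1.  Only
#' intended for small n (the enumeration is exponential).
#'
#' @param a,b numeric vectors.
#' @return Two-sided p-value.
#' @export
mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stopf("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks under ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- combn(na + nb, na)
  us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  min(1, p)
}

#' Two-tailed Mann-Whitney test
#'
#' Exact enumeration when `nA + nB <= 20` and the data are tie-free;
#' otherwise the normal approximation with midranks and continuity
#' correction (delegated to [stats::wilcox.test()]).  When every value in
#' both groups is identical the test is degenerate and p = 1 by convention.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param metric optional metric name carried into the result.
#' @param labels group labels (length 2).
#' @return A one-row `data.frame` (class `group_comparison`): metric,
#'   group_a, group_b, n_a, n_b, statistic (U), p_value, adjusted_p,
#'   stars.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "asymptotic"),
                         metric = NA_character_, labels = c("A", "B")) {
  mode <- match.arg(mode)
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1L) {
    u <- na * nb / 2; p <- 1
  } else {
    exact <- switch(mode,
                    exact = TRUE,
                    asymptotic = FALSE,
                    auto = (na + nb <= 20) && !ties)
    if (exact && ties) {
      # exact enumeration with midranks
      u <- sum(rank(c(a, b))[seq_len(na)]) - na * (na + 1) / 2
      p <- mw_exact_p(a, b)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                         correct = TRUE))
      u <- unname(wt$statistic)
      p <- wt$p.value
    }
  }
  out <- data.frame(metric = metric, group_a = labels[1], group_b = labels[2],
                    n_a = na, n_b = nb, statistic = u, p_value = p,
                    adjusted_p = p, stars = significance_stars(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Kruskal-Wallis test with Dunn's post tests
#'
#' Tie-corrected Kruskal-Wallis H over all groups, followed by pairwise
#' Dunn z-tests on the pooled midranks with Bonferroni family-wise
#' adjustment (the classic "Dunn's post-test").  Adjusted p-values are
#' never smaller than the unadjusted ones.
#'
#' @param groups named list of >= 3 non-empty numeric vectors.
#' @param metric optional metric name.
#' @return List with `H`, `df`, `p_value` (omnibus) and `pairwise` (a
#'   `group_comparison` data frame, one row per pair, with Dunn z as the
#'   statistic and Bonferroni-adjusted p).
#' @export
kruskal_dunn <- function(groups, metric = NA_character_) {
  k <- length(groups)
  if (k < 3) stopf("need >= 3 groups (got %d); use mann_whitney() for 2", k)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stopf("all groups must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kw <- kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  pairs <- combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    se <- sqrt(s2 * (1 / n[[ga]] + 1 / n[[gb]]))
    z <- if (se > 0) (rbar[[ga]] - rbar[[gb]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    data.frame(metric = metric, group_a = ga, group_b = gb,
               n_a = n[[ga]], n_b = n[[gb]], statistic = z, p_value = p,
               adjusted_p = min(1, p * m),
               stars = significance_stars(min(1, p * m)),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  class(pw) <- c("group_comparison", class(pw))
  H <- unname(kw$statistic); pv <- kw$p.value
  if (!is.finite(H)) { H <- 0; pv <- 1 }  # all values identical
  list(H = H, df = unname(kw$parameter), p_value = pv, pairwise = pw)
}
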