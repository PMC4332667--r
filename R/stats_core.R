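#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA computed from between- and within-group sums of
#' squares. Used as the omnibus screen when comparing mean expression
#' Z-scores of an orthologous cluster across organs.
#'
#' If every group has zero within-group variance and all group means are
#' equal (a completely flat cluster), the test is degenerate and the
#' function returns `f_stat = 0`, `p_value = 1`. If the within-group sum of
#' squares is zero but the means differ, `f_stat = Inf`, `p_value = 0`.
#'
#' @param sample A named list of numeric vectors, one per group, in group
#'   order. At least two groups, every group nonempty, all values finite.
#' @return A list with `f_stat`, `p_value`, `df_between`, `df_within`,
#'   `ms_within`, and `group_means` (named).
#' @seealso [tukey_hsd()] for the post-hoc pairwise comparisons.
#' @export
anova_oneway <- function(sample) {
  sample <- check_grouped(sample)
  k <- length(sample)
  n_i <- lengths(sample)
  n <- sum(n_i)
  if (n <= k) {
    stop_input("one-way ANOVA needs more observations (%d) than groups (%d)", n, k)
  }
  m_i <- vapply(sample, mean, numeric(1))
  grand <- sum(n_i * m_i) / n
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) {
    sum((sample[[i]] - m_i[i])^2)
  }, numeric(1)))
  df_b <- k - 1L
  df_w <- n - k
  ms_within <- ss_within / df_w
  if (ss_within == 0) {
    if (ss_between <= .Machine$double.eps * max(1, grand^2) * n) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ss_between / df_b) / ms_within
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(f_stat = f, p_value = p, df_between = df_b, df_within = df_w,
       ms_within = ms_within, group_means = m_i)
}

#' Tukey HSD all-pairs comparisons
#'
#' Studentized-range adjusted p-values for every unordered pair of groups,
#' with the within-group mean square pooled across all groups. Unequal
#' group sizes use the Tukey--Kramer harmonic-mean form. Six organs give
#' the 15 pairwise results used by the OSER screen.
#'
#' @inheritParams anova_oneway
#' @param alpha Familywise significance level used to flag pairs
#'   (default 0.05).
#' @return A data.frame with one row per unordered pair in group order:
#'   `group1`, `group2`, `mean_diff` (first minus second), `adj_p`,
#'   `significant`.
#' @export
tukey_hsd <- function(sample, alpha = 0.05) {
  sample <- check_grouped(sample)
  fit <- anova_oneway(sample)
  k <- length(sample)
  labs <- names(sample)
  n_i <- lengths(sample)
  m_i <- fit$group_means
  idx <- utils::combn(k, 2L)
  g1 <- idx[1L, ]; g2 <- idx[2L, ]
  diff <- m_i[g1] - m_i[g2]
  if (fit$ms_within == 0) {
    adj_p <- ifelse(abs(diff) <= .Machine$double.eps * pmax(1, abs(m_i[g1])), 1, 0)
  } else {
    se <- sqrt(fit$ms_within / 2 * (1 / n_i[g1] + 1 / n_i[g2]))
    q <- abs(diff) / se
    adj_p <- stats::ptukey(q, nmeans = k, df = fit$df_within, lower.tail = FALSE)
  }
  adj_p <- pmin(pmax(adj_p, 0), 1)
  data.frame(group1 = labs[g1], group2 = labs[g2],
             mean_diff = unname(diff), adj_p = unname(adj_p),
             significant = unname(adj_p < alpha),
             stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Exact by full enumeration of rank assignments when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with continuity and tie corrections. The reported
#' statistic is the Mann-Whitney U of the first sample.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact_max Combined-size threshold for the exact path (default 12).
#' @return A list with `statistic` (U of `x`) and `p_value`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_input("rank_sum_test requires two nonempty samples")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_input("rank_sum_test requires finite observations")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n <= exact_max) {
    p <- rank_sum_exact_p(u, n1, n2)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (u == mu) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = unname(u), p_value = p)
}

# exact two-sided p by enumerating all C(n, n1) rank assignments
rank_sum_exact_p <- function(u, n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  u_all <- colSums(combos) - n1 * (n1 + 1) / 2
  if (u > n1 * n2 / 2) {
    p <- 2 * mean(u_all >= u)
  } else if (u < n1 * n2 / 2) {
    p <- 2 * mean(u_all <= u)
  } else {
    p <- 1
  }
  min(1, p)
}

check_grouped <- function(sample) {
  if (!is.list(sample) || length(sample) < 2L) {
    stop_input("grouped sample must be a list of at least 2 groups")
  }
  if (is.null(names(sample)) || anyDuplicated(names(sample)) || any(names(sample) == "")) {
    stop_input("groups must carry unique nonempty names")
  }
  if (any(lengths(sample) == 0L)) {
    empty <- names(sample)[lengths(sample) == 0L]
    stop_input("empty group(s): %s", paste(empty, collapse = ", "))
  }
  sample <- lapply(sample, as.numeric)
  if (!all(vapply(sample, function(v) all(is.finite(v)), logical(1)))) {
    stop_input("all observations must be finite")
  }
  sample
}
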