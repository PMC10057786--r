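#' Spearman rank correlation with the S statistic
#'
#' Ranks both vectors (mid-ranks for ties) and reports the rank-difference
#' statistic `S = sum((rank_x - rank_y)^2)` together with rho. Without ties
#' rho is computed from S as `1 - 6 S / (n (n^2 - 1))`; with ties it is the
#' Pearson correlation of the rank vectors. The two-sided p-value comes from
#' [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @return A one-row tibble: `n`, `S`, `rho`, `p_value`.
#' @export
#' @examples
#' spearman_rank(1:5, c(2, 1, 4, 3, 5))
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs n >= 3 complete pairs.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Spearman rho is undefined for a constant vector.",
          class = "peatsense_undefined_index")
  }
  rx <- rank(x); ry <- rank(y)
  s <- sum((rx - ry)^2)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  rho <- if (ties) cor(rx, ry) else spearman_rho_from_s(s, n)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble(n = n, S = s, rho = rho, p_value = ct$p.value)
}

#' Convert a Spearman S statistic to rho
#'
#' For tie-free ranks, `rho = 1 - 6 S / (n (n^2 - 1))`; useful for checking
#' the internal consistency of reported (S, rho) pairs.
#'
#' @param s The rank-difference statistic `sum(d^2)`.
#' @param n Number of pairs.
#' @return rho.
#' @export
#' @examples
#' spearman_rho_from_s(366, 11)  # -0.664
spearman_rho_from_s <- function(s, n) {
  stopifnot(n >= 2, s >= 0)
  1 - 6 * s / (n * (n^2 - 1))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test with the W statistic in the convention of
#' [stats::wilcox.test()]: W is the Mann-Whitney U of the first group, i.e.
#' the rank sum of `a` in the pooled mid-ranking minus `n_a (n_a + 1) / 2`,
#' ranging over `[0, n_a * n_b]`. The p-value is two-sided: exact when the
#' samples are small (`n_a * n_b <= 400`) and tie-free, otherwise a normal
#' approximation with continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return A one-row tibble: `W`, `n_a`, `n_b`, `p_value`.
#' @export
#' @examples
#' rank_sum_w(6:10, 1:5)  # complete separation: W = 25
rank_sum_w <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups must be non-empty.")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) * length(b) <= 400 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  tibble(W = unname(wt$statistic), n_a = length(a), n_b = length(b),
         p_value = wt$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with `k - 1` degrees of freedom and a
#' chi-squared p-value. When every observation is identical the statistic is
#' undefined and is reported as such rather than silently returned as zero.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; >= 2 non-empty
#'   groups.
#' @return A one-row tibble: `H`, `df`, `p_value`, `n_groups`, `undefined`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) abort("Need at least two non-empty groups.")
  if (length(unique(values)) == 1) {
    warn("All observations identical; Kruskal-Wallis H is undefined.")
    return(tibble(H = NA_real_, df = nlevels(groups) - 1L,
                  p_value = NA_real_, n_groups = nlevels(groups),
                  undefined = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n_groups = nlevels(groups), undefined = FALSE)
}

#' Pairwise rank-sum tests with Bonferroni adjustment
#'
#' All `k (k - 1) / 2` two-sided rank-sum comparisons between groups, with
#' family-wise correction `p_adj = min(1, p * m)` where `m` is the number of
#' comparisons.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble with one row per pair: `group1`, `group2`, `p_value`,
#'   `p_adj`, `m`.
#' @export
pairwise_wilcoxon_bonferroni <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  if (any(table(groups) == 0)) abort("Every group must be non-empty.")
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    res <- rank_sum_w(values[groups == pairs[1, j]],
                      values[groups == pairs[2, j]])
    tibble(group1 = pairs[1, j], group2 = pairs[2, j],
           p_value = res$p_value)
  })
  out <- bind_rows(rows)
  out$p_adj <- pmin(1, out$p_value * m)
  out$m <- m
  out
}
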