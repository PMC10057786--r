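#' Tidy the correlation screen of a peat analysis
#'
#' Broom-style accessor: one row per Spearman correlation computed by
#' [run_analysis()], with scope (`upper50` or `whole_profile`), variable
#' pair, S, rho and p-value.
#'
#' @param x A `peat_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.peat_analysis <- function(x, ...) {
  x$correlation_table
}

#' One-row summary of a peat analysis
#'
#' @inheritParams tidy.peat_analysis
#' @return A one-row tibble with the headline quantities: the two upper-50 cm
#'   correlations, the peat-to-vegetation median stock ratio and its
#'   rank-sum test.
#' @export
glance.peat_analysis <- function(x, ...) {
  up <- x$correlation_table
  row1 <- up[up$var_x == "upper50_stock_mg_ha" & up$var_y == "nbr_sd", ]
  row2 <- up[up$var_x == "upper50_HI" & up$var_y == "nbr_mean", ]
  w <- x$tests[x$tests$test == "wilcoxon_rank_sum", ]
  tibble(
    n_sites = nrow(x$site_table),
    n_samples = nrow(x$ir_table),
    rho_upper50_stock_nbr_sd = row1$rho,
    p_upper50_stock_nbr_sd = row1$p_value,
    rho_upper50_hi_nbr_mean = row2$rho,
    p_upper50_hi_nbr_mean = row2$p_value,
    peat_veg_median_ratio = median(x$stocks$peat_stock_mg_ha) /
      median(x$stocks$veg_stock_mg_ha),
    W_peat_veg = w$statistic,
    p_peat_veg = w$p_value
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
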