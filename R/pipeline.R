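#' Median and IQR summaries of thermal indices per class and depth layer
#'
#' Summarises R- and I-index values (or any index columns) by forest
#' condition class within each depth layer, and additionally for the pooled
#' "disturbed" grouping (DisturbedForest + FireAffected + ManagedRecovery)
#' against CentralForest. Quartiles use linear interpolation (R type 7).
#' Undefined (NA) index values are excluded from the summaries and counted;
#' empty class-by-layer cells are simply absent from the output.
#'
#' @param samples A data frame with `class`, `layer` and the index columns.
#' @param index_cols Character vector of index columns to summarise.
#' @return A tibble with `grouping` (`"class"` or `"pooled"`), `class`,
#'   `layer`, `n`, and `<index>_median` / `<index>_iqr` / `<index>_n_undefined`
#'   columns.
#' @export
#' @examples
#' df <- tibble::tibble(class = "CentralForest", layer = "upper50",
#'                      r_index = c(0.52, 0.56, 0.60))
#' summarise_layers(df, "r_index")
summarise_layers <- function(samples, index_cols = c("r_index", "i_index")) {
  stopifnot(all(c("class", "layer") %in% names(samples)),
            all(index_cols %in% names(samples)))
  summarise_one <- function(df) {
    out <- summarise(df, n = n(), .groups = "drop")
    for (col in index_cols) {
      v <- df |> summarise(
        med = median(.data[[col]], na.rm = TRUE),
        iqr = stats::IQR(.data[[col]], na.rm = TRUE, type = 7),
        nu = sum(is.na(.data[[col]])), .groups = "drop")
      out[[paste0(col, "_median")]] <- v$med
      out[[paste0(col, "_iqr")]] <- v$iqr
      out[[paste0(col, "_n_undefined")]] <- v$nu
    }
    out
  }
  by_class <- samples |>
    group_by(.data$class, .data$layer) |>
    summarise_one() |>
    mutate(grouping = "class")
  pooled <- samples |>
    mutate(class = ifelse(.data$class == "CentralForest",
                          "CentralForest", "disturbed")) |>
    group_by(.data$class, .data$layer) |>
    summarise_one() |>
    mutate(grouping = "pooled")
  bind_rows(by_class, pooled) |>
    dplyr::relocate("grouping") |>
    ungroup()
}

# Per-sample Rock-Eval results for every core of a study, with depth layers.
study_rockeval <- function(study) {
  rows <- lapply(study$cores, function(co) {
    res <- rockeval_table(co$pyrograms)
    meta <- select(co$segments, "sample_id", "site_id", "class",
                   "top_cm", "bottom_cm")
    res |>
      left_join(meta, by = "sample_id") |>
      mutate(
        site_id = ifelse(is.na(.data$site_id), co$scenario$site_id,
                         .data$site_id),
        class = ifelse(is.na(.data$class), co$scenario$condition_class,
                       .data$class),
        layer = ifelse(
          is.na(.data$top_cm), "litter",
          classify_depth_layer(
            dplyr::coalesce(.data$top_cm, 0),
            dplyr::coalesce(.data$bottom_cm, 1),
            water_table_cm = co$scenario$water_table_depth * 100,
            clay_top_cm = round(co$scenario$peat_depth * 10) * 10))
      )
  })
  bind_rows(rows)
}

#' Run the coupled geochemistry / remote-sensing analysis
#'
#' End-to-end pipeline: generate (or accept) a study dataset, compute
#' Rock-Eval parameters and thermal-stability indices for every analysed
#' sample, peat and vegetation carbon stocks per site, NBR stack statistics
#' with site-level extraction and river/canal distances, and finally the
#' rank-based comparisons: Spearman correlations of upper-50 cm stock vs
#' NBR temporal sd and upper-50 cm HI vs NBR mean, a whole-profile
#' correlation screen against all covariates, the peat-vs-vegetation
#' rank-sum test, and Kruskal-Wallis plus pairwise-Wilcoxon comparisons of
#' the indices between classes. Deterministic under a fixed seed.
#'
#' @param config A [study_config()].
#' @param seed Integer seed passed to [generate_study()].
#' @return A `peat_analysis` object; see [tidy.peat_analysis()],
#'   [glance.peat_analysis()], [autoplot.peat_analysis()] and
#'   [write_report()].
#' @export
#' @examples
#' \donttest{
#' fit <- run_analysis(seed = 1)
#' glance(fit)
#' }
run_analysis <- function(config = study_config(), seed = 1) {
  analyse_study(generate_study(config, seed = seed))
}

#' @rdname run_analysis
#' @param study A [generate_study()] result (allows re-analysis of a
#'   persisted or externally built dataset).
#' @export
analyse_study <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  rockeval <- study_rockeval(study)

  # carbon stocks: join measured TOC onto segments, interpolate the rest
  segs <- study$segments |>
    left_join(select(rockeval, "sample_id", toc_wt_pct = "TOC"),
              by = "sample_id")
  stocks <- core_stocks(segs) |>
    left_join(select(study$sites, "site_id", "class", "agb_mg_ha"),
              by = "site_id") |>
    mutate(veg_stock_mg_ha = vegetation_stock(.data$agb_mg_ha))

  # remote sensing covariates
  products <- stack_stats(study$stack)
  covariates <- extract_at_sites(products, study$sites) |>
    mutate(dist_river_m = distance_to_line(study$sites, study$river),
           dist_canal_m = distance_to_line(study$sites, study$canals)) |>
    select("site_id", "nbr_mean", "nbr_sd", "dist_river_m", "dist_canal_m")

  # site-level aggregates of the Rock-Eval results
  peat_samples <- filter(rockeval, .data$layer != "litter")
  upper <- peat_samples |>
    filter(.data$layer == "upper50") |>
    group_by(.data$site_id) |>
    summarise(upper50_HI = mean(.data$HI), .groups = "drop")
  whole <- peat_samples |>
    group_by(.data$site_id) |>
    summarise(HI_mean = mean(.data$HI), OI_mean = mean(.data$OI),
              r_index_mean = mean(.data$r_index, na.rm = TRUE),
              i_index_mean = mean(.data$i_index, na.rm = TRUE),
              .groups = "drop")
  site_table <- stocks |>
    left_join(upper, by = "site_id") |>
    left_join(whole, by = "site_id") |>
    left_join(covariates, by = "site_id")

  # correlation screen
  cor_row <- function(var_x, var_y, scope) {
    res <- spearman_rank(site_table[[var_x]], site_table[[var_y]])
    tibble(scope = scope, var_x = var_x, var_y = var_y,
           n = res$n, S = res$S, rho = res$rho, p_value = res$p_value)
  }
  upper_pairs <- list(c("upper50_stock_mg_ha", "nbr_sd"),
                      c("upper50_HI", "nbr_mean"))
  whole_vars <- c("peat_stock_mg_ha", "HI_mean", "OI_mean",
                  "r_index_mean", "i_index_mean")
  covs <- c("nbr_mean", "nbr_sd", "dist_river_m", "dist_canal_m")
  correlation_table <- bind_rows(
    lapply(upper_pairs, function(p) cor_row(p[1], p[2], "upper50")),
    lapply(whole_vars, function(v)
      bind_rows(lapply(covs, function(cv) cor_row(v, cv, "whole_profile"))))
  )

  # group comparisons
  w_pv <- rank_sum_w(stocks$peat_stock_mg_ha, stocks$veg_stock_mg_ha)
  up <- filter(rockeval, .data$layer == "upper50")
  lower <- filter(rockeval, .data$layer %in% c("below_water_table", "deep"))
  kw <- bind_rows(
    mutate(kruskal_wallis(up$r_index, up$class),
           test = "kruskal_wallis", variable = "r_index", layer = "upper50"),
    mutate(kruskal_wallis(up$i_index, up$class),
           test = "kruskal_wallis", variable = "i_index", layer = "upper50"),
    mutate(kruskal_wallis(lower$r_index, lower$class),
           test = "kruskal_wallis", variable = "r_index",
           layer = "below_wt_deep"),
    mutate(kruskal_wallis(lower$i_index, lower$class),
           test = "kruskal_wallis", variable = "i_index",
           layer = "below_wt_deep")
  )
  tests <- bind_rows(
    tibble(test = "wilcoxon_rank_sum", variable = "peat_vs_veg_stock",
           layer = "whole_profile", statistic = w_pv$W,
           p_value = w_pv$p_value),
    select(kw, "test", "variable", "layer", statistic = "H", "p_value")
  )
  pairwise <- list(
    r_index_upper50 = pairwise_wilcoxon_bonferroni(up$r_index, up$class),
    i_index_upper50 = pairwise_wilcoxon_bonferroni(up$i_index, up$class)
  )

  ir_table <- select(rockeval, "sample_id", "site_id", "class", "layer",
                     "r_index", "i_index")
  hi_oi_table <- select(rockeval, "sample_id", "site_id", "class", "layer",
                        "HI", "OI")

  structure(
    list(ir_table = ir_table, hi_oi_table = hi_oi_table,
         rockeval = rockeval,
         layer_summaries = summarise_layers(ir_table),
         correlation_table = correlation_table,
         site_table = site_table, stocks = stocks,
         covariates = covariates, tests = tests, pairwise = pairwise,
         products = products,
         provenance = list(seed = study$seed,
                           config_hash = rlang::hash(study$config),
                           package_version =
                             as.character(utils::packageVersion("peatsense")))),
    class = "peat_analysis"
  )
}

#' @export
print.peat_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<peat_analysis> ", g$n_sites, " sites, ", g$n_samples,
      " Rock-Eval samples (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  upper-50 cm stock vs NBR sd:   rho = ",
      sprintf("%.3f", g$rho_upper50_stock_nbr_sd),
      " (p = ", sprintf("%.4f", g$p_upper50_stock_nbr_sd), ")\n", sep = "")
  cat("  upper-50 cm HI vs NBR mean:    rho = ",
      sprintf("%.3f", g$rho_upper50_hi_nbr_mean),
      " (p = ", sprintf("%.4f", g$p_upper50_hi_nbr_mean), ")\n", sep = "")
  cat("  peat : vegetation stock medians = ",
      sprintf("%.1f", g$peat_veg_median_ratio), " (W = ", g$W_peat_veg,
      ", p = ", format.pval(g$p_peat_veg, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Write the analysis report tables
#'
#' Persists the analysis as a directory of CSVs (I/R diagram data,
#' HI/OI data, layer summaries, correlation screen, test results, stocks and
#' site covariates), the NBR mean/sd rasters as ASCII grids, and a
#' provenance JSON (seed, config hash, package version). Writing is
#' deterministic: the same analysis writes byte-identical files.
#'
#' @param analysis A `peat_analysis`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "peat_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) readr::write_csv(df, file.path(dir, name),
                                            progress = FALSE)
  wr(analysis$ir_table, "ir_table.csv")
  wr(analysis$hi_oi_table, "hi_oi_table.csv")
  wr(analysis$layer_summaries, "layer_summaries.csv")
  wr(analysis$correlation_table, "correlations.csv")
  wr(analysis$tests, "tests.csv")
  wr(analysis$pairwise$r_index_upper50, "pairwise_r_index_upper50.csv")
  wr(analysis$pairwise$i_index_upper50, "pairwise_i_index_upper50.csv")
  wr(analysis$stocks, "core_stocks.csv")
  wr(analysis$covariates, "site_covariates.csv")
  pr <- analysis$products
  ymin <- pr$ymax - nrow(pr$nbr_mean) * pr$res_m
  write_ascii_grid(pr$nbr_mean, file.path(dir, "nbr_mean.asc"),
                   xmin = pr$xmin, ymin = ymin, res_m = pr$res_m)
  write_ascii_grid(pr$nbr_sd, file.path(dir, "nbr_sd.asc"),
                   xmin = pr$xmin, ymin = ymin, res_m = pr$res_m)
  jsonlite::write_json(analysis$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
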