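layer_levels <- c("litter", "upper50", "below_water_table", "deep", "other")

#' I/R diagram of thermal-stability indices
#'
#' Scatter of I-index against R-index per sample, coloured by depth layer
#' and shaped by forest condition class. Pristine profiles trace the
#' expected decomposition trend (I falling as R rises with depth); disturbed
#' profiles place their upper-50 cm samples at the thermally stabilised
#' (low-I, high-R) tail.
#'
#' @param ir_table A data frame with `class`, `layer`, `r_index`, `i_index`
#'   (e.g. `fit$ir_table` from [run_analysis()]).
#' @return A ggplot object.
#' @export
plot_ir_diagram <- function(ir_table) {
  df <- filter(ir_table, !is.na(.data$r_index), !is.na(.data$i_index)) |>
    mutate(layer = factor(.data$layer, levels = layer_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_index, y = .data$i_index,
                                   colour = .data$layer,
                                   shape = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "R-index (refractory OM)", y = "I-index (immature OM)",
                  colour = "Depth layer", shape = "Condition class") +
    ggplot2::theme_minimal()
}

#' Pseudo van Krevelen diagram (HI vs OI)
#'
#' @param hi_oi_table A data frame with `class`, `layer`, `HI`, `OI`.
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(hi_oi_table) {
  df <- mutate(hi_oi_table, layer = factor(.data$layer,
                                           levels = layer_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$OI, y = .data$HI,
                                   colour = .data$layer,
                                   shape = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "OI (mg O2 as CO2 / g TOC)", y = "HI (mg HC / g TOC)",
                  colour = "Depth layer", shape = "Condition class") +
    ggplot2::theme_minimal()
}

raster_df <- function(m, geo) {
  tibble(
    x = rep((seq_len(ncol(m)) - 0.5) * geo$res_m + geo$xmin,
            each = nrow(m)),
    y = rep(geo$ymax - (seq_len(nrow(m)) - 0.5) * geo$res_m,
            times = ncol(m)),
    value = as.vector(m)
  )
}

#' Map the NBR stack products
#'
#' @param object An `nbr_products` result from [stack_stats()].
#' @param layer `"nbr_mean"` or `"nbr_sd"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbr_products <- function(object, layer = c("nbr_mean", "nbr_sd"),
                                  ...) {
  layer <- match.arg(layer)
  df <- raster_df(object[[layer]], object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = layer) +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot a peat analysis
#'
#' @param object A `peat_analysis` from [run_analysis()].
#' @param type `"ir"` (I/R diagram), `"van_krevelen"` (HI vs OI),
#'   `"correlation"` (the two headline upper-50 cm site scatters) or
#'   `"nbr"` (NBR sd map).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peat_analysis <- function(object,
                                   type = c("ir", "van_krevelen",
                                            "correlation", "nbr"), ...) {
  type <- match.arg(type)
  if (type == "ir") return(plot_ir_diagram(object$ir_table))
  if (type == "van_krevelen") return(plot_van_krevelen(object$hi_oi_table))
  if (type == "nbr") return(autoplot.nbr_products(object$products, "nbr_sd"))
  df <- tidyr::pivot_longer(
    select(object$site_table, "site_id", "class", "upper50_stock_mg_ha",
           "upper50_HI", "nbr_mean", "nbr_sd"),
    cols = c("upper50_stock_mg_ha", "upper50_HI"),
    names_to = "response", values_to = "value") |>
    mutate(covariate = ifelse(.data$response == "upper50_stock_mg_ha",
                              .data$nbr_sd, .data$nbr_mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$covariate, y = .data$value,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~response, scales = "free") +
    ggplot2::labs(x = "NBR covariate (sd for stock, mean for HI)",
                  y = NULL, colour = "Condition class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
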