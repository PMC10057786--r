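#' Sampling-chamber volume of a Russian peat corer
#'
#' The side-filling Russian corer extracts a half-cylinder of peat; a 10 cm
#' increment from a chamber of radius 2.5 cm has volume
#' pi * r^2 * L / 2 = 98.17 cm^3, the constant used to convert segment dry
#' mass to bulk density.
#'
#' @param radius_cm Chamber radius (cm).
#' @param length_cm Increment length (cm).
#' @return Volume in cm^3.
#' @export
#' @examples
#' corer_volume_cm3()  # 98.17
corer_volume_cm3 <- function(radius_cm = 2.5, length_cm = 10) {
  stopifnot(radius_cm > 0, length_cm > 0)
  pi * radius_cm^2 * length_cm / 2
}

#' Bulk density of a peat segment
#'
#' Oven-dry mass divided by the fresh sample volume.
#'
#' @param dry_g Oven-dry mass (g), >= 0. Vectorised.
#' @param volume_cm3 Sample volume (cm^3), > 0; defaults to the Russian-corer
#'   10 cm increment, [corer_volume_cm3()].
#' @return Bulk density (g cm^-3).
#' @export
#' @examples
#' bulk_density(9.817)  # ~0.10 g cm^-3, a typical tropical peat value
bulk_density <- function(dry_g, volume_cm3 = corer_volume_cm3()) {
  if (any(volume_cm3 <= 0)) abort("`volume_cm3` must be > 0.")
  if (any(dry_g < 0)) abort("`dry_g` must be >= 0.")
  dry_g / volume_cm3
}

#' Carbon density of a peat segment
#'
#' Bulk density times the organic-carbon mass fraction times the segment
#' thickness: `bd * (toc/100) * thickness`, in g C per cm^2 of ground area.
#'
#' @param bd Bulk density (g cm^-3). Vectorised.
#' @param toc_wt_pct Total organic carbon (wt %), 0-100.
#' @param thickness_cm Segment thickness (cm), default 10.
#' @return Carbon density (g cm^-2).
#' @export
#' @examples
#' segment_carbon_density(0.1, 50)  # 0.5 g cm^-2
segment_carbon_density <- function(bd, toc_wt_pct, thickness_cm = 10) {
  if (any(bd < 0) || any(thickness_cm < 0)) {
    abort("`bd` and `thickness_cm` must be >= 0.")
  }
  if (any(toc_wt_pct < 0 | toc_wt_pct > 100, na.rm = TRUE)) {
    abort("`toc_wt_pct` must lie in [0, 100].")
  }
  bd * (toc_wt_pct / 100) * thickness_cm
}

#' Unit conversion between g cm^-2 and Mg ha^-1
#'
#' The whole mass-unit chain lives here: 1 g cm^-2 = 10^4 g m^-2 =
#' 10^8 g ha^-1 = 100 Mg ha^-1.
#'
#' @param x Value(s) to convert.
#' @return Converted value(s).
#' @export
g_cm2_to_mg_ha <- function(x) 100 * x

#' @rdname g_cm2_to_mg_ha
#' @export
mg_ha_to_g_cm2 <- function(x) x / 100

# Fill unmeasured TOC by linear depth-interpolation between measured
# neighbours (constant extrapolation at core ends), using segment midpoints.
interpolate_toc <- function(mid_cm, toc) {
  measured <- !is.na(toc)
  if (!any(measured)) abort("Core has no measured TOC; cannot compute stock.")
  if (sum(measured) == 1) return(rep(toc[measured], length(toc)))
  stats::approx(mid_cm[measured], toc[measured], xout = mid_cm, rule = 2)$y
}

#' Carbon stock of a peat core
#'
#' Sums per-segment carbon densities over the profile and converts to
#' Mg ha^-1 (see [g_cm2_to_mg_ha()]). TOC is typically measured on selected
#' sub-samples only; unmeasured segments take linearly depth-interpolated
#' TOC between measured neighbours (constant-extrapolated at the core ends).
#' The upper-50 cm stock is the same sum restricted to segments whose bottom
#' lies within 50 cm of the surface.
#'
#' @param segments A data frame with one row per contiguous segment of a
#'   single core: `top_cm`, `bottom_cm`, a bulk-density source (either
#'   `bulk_density_g_cm3` or `dry_g` plus optional `volume_cm3`), and
#'   `toc_wt_pct` (NA for unmeasured segments).
#'
#' @return A one-row tibble: `peat_stock_mg_ha`, `upper50_stock_mg_ha`,
#'   `peat_depth_m`, `n_segments`, `n_toc_measured`.
#' @export
#' @examples
#' segs <- tibble::tibble(top_cm = seq(0, 40, 10), bottom_cm = seq(10, 50, 10),
#'                        bulk_density_g_cm3 = 0.1, toc_wt_pct = 50)
#' core_stock(segs)  # 5 x 0.5 g cm^-2 = 250 Mg ha^-1
core_stock <- function(segments) {
  stopifnot(is.data.frame(segments), nrow(segments) > 0)
  segments <- arrange(as_tibble(segments), .data$top_cm)
  if (any(segments$bottom_cm <= segments$top_cm)) {
    abort("Segments need top_cm < bottom_cm.")
  }
  if (any(abs(segments$top_cm[-1] - segments$bottom_cm[-nrow(segments)]) > 1e-9)) {
    abort("Segments must be contiguous from the surface to the clay.")
  }
  bd <- if ("bulk_density_g_cm3" %in% names(segments)) {
    segments$bulk_density_g_cm3
  } else if ("dry_g" %in% names(segments)) {
    vol <- segments[["volume_cm3"]] %||% corer_volume_cm3()
    bulk_density(segments$dry_g, vol)
  } else {
    abort("Segments need `bulk_density_g_cm3` or `dry_g`.")
  }
  mid <- (segments$top_cm + segments$bottom_cm) / 2
  toc <- interpolate_toc(mid, segments$toc_wt_pct)
  dens <- segment_carbon_density(bd, toc, segments$bottom_cm - segments$top_cm)
  upper <- segments$bottom_cm <= 50
  tibble(
    peat_stock_mg_ha = g_cm2_to_mg_ha(sum(dens)),
    upper50_stock_mg_ha = g_cm2_to_mg_ha(sum(dens[upper])),
    peat_depth_m = max(segments$bottom_cm) / 100,
    n_segments = nrow(segments),
    n_toc_measured = sum(!is.na(segments$toc_wt_pct))
  )
}

#' Carbon stocks for all cores in a segment table
#'
#' @param segments A data frame of segments for several cores, with a
#'   `site_id` column plus the [core_stock()] columns.
#' @return A tibble, one row per site.
#' @export
core_stocks <- function(segments) {
  stopifnot("site_id" %in% names(segments))
  segments |>
    group_by(.data$site_id) |>
    dplyr::group_modify(~ core_stock(.x)) |>
    ungroup()
}

#' Vegetation carbon stock from above-ground biomass
#'
#' Applies a carbon-content conversion factor (default 0.47) to an
#' above-ground biomass estimate.
#'
#' @param agb_mg_ha Above-ground biomass (Mg ha^-1), >= 0. Vectorised.
#' @param carbon_fraction Carbon content of biomass, default 0.47.
#' @return Vegetation carbon stock (Mg ha^-1).
#' @export
#' @examples
#' vegetation_stock(244.04)  # 114.70 Mg ha^-1
vegetation_stock <- function(agb_mg_ha, carbon_fraction = 0.47) {
  if (any(agb_mg_ha < 0)) abort("`agb_mg_ha` must be >= 0.")
  stopifnot(carbon_fraction >= 0, carbon_fraction <= 1)
  carbon_fraction * agb_mg_ha
}
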