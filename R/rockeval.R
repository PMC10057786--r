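# S2 node windows (degC): A1 200-340, A2 340-400, A3 400-460, A4 > 460.
# Half-open [lo, hi); A4 is unbounded above.
node_breaks <- c(200, 340, 400, 460, Inf)

# Trapezoid integral of y(x) over [lo, hi], linearly interpolating the
# integrand at the window edges so node areas are grid-placement independent.
trapz_window <- function(x, y, lo, hi) {
  hi <- min(hi, max(x))
  lo <- max(lo, min(x))
  if (hi <= lo) return(0)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}

# Ramp-phase signal as a per-degC curve over temperature. Accepts a pyrogram
# (per-second FID over a time axis) or a plain data frame already indexed by
# temperature (columns temp_c, fid_signal), e.g. an instrument export.
ramp_curve <- function(p) {
  if (inherits(p, "pyrogram")) {
    ramp <- p$pyrolysis[p$pyrolysis$phase == "ramp", ]
    if (nrow(ramp) < 2) abort("Pyrogram has no ramp phase.")
    dtemp_dt <- diff(range(ramp$temp_c)) / diff(range(ramp$time_s))
    list(temp_c = ramp$temp_c, signal = ramp$fid_signal / dtemp_dt)
  } else if (is.data.frame(p)) {
    if (!all(c("temp_c", "fid_signal") %in% names(p))) {
      abort("Data-frame pyrograms need columns `temp_c` and `fid_signal`.")
    }
    if (any(diff(p$temp_c) <= 0)) abort("Temperatures must be strictly ascending.")
    list(temp_c = p$temp_c, signal = p$fid_signal)
  } else {
    abort("`p` must be a pyrogram or a data frame.")
  }
}

#' Integrate S2 pyrogram thermal nodes (A1-A4)
#'
#' Splits the S2 pyrogram into the four thermal windows used for
#' organic-matter stability indexing: 200-340 degC (A1, labile fresh plant
#' matter), 340-400 degC (A2, lignin and cellulose), 400-460 degC (A3,
#' humified macromolecules) and > 460 degC (A4, mature recalcitrant matter
#' and char). Trapezoid areas per window are normalised to percentages of the
#' total S2 area.
#'
#' @param p A `pyrogram` (see [generate_pyrogram()]) or a data frame with
#'   strictly ascending `temp_c` and per-degC `fid_signal` covering the ramp.
#'
#' @return A one-row tibble with columns `A1`, `A2`, `A3`, `A4` (percent,
#'   summing to 100).
#' @export
#' @examples
#' p <- generate_pyrogram(thermal_composition(310, 15, 1), total_s2 = 50)
#' integrate_s2_nodes(p)  # essentially all mass in A1
integrate_s2_nodes <- function(p) {
  curve <- ramp_curve(p)
  if (max(curve$temp_c) < 460) {
    abort("Pyrolysis ramp must reach at least 460 degC to resolve node A4.")
  }
  areas <- vapply(seq_len(4), function(k) {
    trapz_window(curve$temp_c, curve$signal, node_breaks[k], node_breaks[k + 1])
  }, numeric(1))
  total <- sum(areas)
  if (!is.finite(total) || total <= 0) {
    abort("Total S2 area is zero; node percentages are undefined.",
          class = "peatsense_undefined_index")
  }
  pct <- 100 * areas / total
  tb(A1 = pct[1], A2 = pct[2], A3 = pct[3], A4 = pct[4])
}

check_nodes <- function(nodes) {
  if (!all(c("A1", "A2", "A3", "A4") %in% names(nodes))) {
    abort("Node areas need columns A1, A2, A3, A4.")
  }
  tot <- nodes$A1 + nodes$A2 + nodes$A3 + nodes$A4
  if (any(abs(tot - 100) > 1e-6)) {
    abort("Node percentages must sum to 100 (within 1e-6).")
  }
  invisible(nodes)
}

#' Thermal-stability indices from S2 node areas
#'
#' The R-index (refractory organic-matter index) is the fraction of S2 area
#' in the thermally stable windows, `(A3 + A4) / 100`; it rises as organic
#' matter decomposes. The I-index (immature organic-matter index) is
#' `log10((A1 + A2) / A3)`; it falls with decomposition. Together they trace
#' decomposition state on the I/R diagram: pristine peat profiles drift from
#' high-I/low-R near the surface towards low-I/high-R at depth, while
#' disturbed profiles show thermally stabilised (low-I, high-R) surface peat.
#'
#' @param nodes A tibble with columns `A1`-`A4` in percent (rows are samples),
#'   e.g. from [integrate_s2_nodes()].
#'
#' @return A numeric vector, one value per row of `nodes`. `i_index()` is
#'   undefined where `A3 = 0` or `A1 + A2 = 0`; such rows are returned as
#'   `NA` with a warning rather than dropped.
#' @export
#' @examples
#' n <- tibble::tibble(A1 = 30, A2 = 30, A3 = 6, A4 = 34)
#' r_index(n)  # 0.4
#' i_index(n)  # 1
r_index <- function(nodes) {
  check_nodes(nodes)
  (nodes$A3 + nodes$A4) / 100
}

#' @rdname r_index
#' @export
i_index <- function(nodes) {
  check_nodes(nodes)
  undefined <- nodes$A3 <= 0 | (nodes$A1 + nodes$A2) <= 0
  if (any(undefined)) {
    warn(sprintf("I-index undefined for %d sample(s) (A3 = 0 or A1 + A2 = 0); returned as NA.",
                 sum(undefined)))
  }
  out <- rep(NA_real_, nrow(nodes))
  ok <- !undefined
  out[ok] <- log10((nodes$A1[ok] + nodes$A2[ok]) / nodes$A3[ok])
  out
}

#' TOC assembly factors
#'
#' Carbon-conversion factors used to assemble total organic carbon (wt %)
#' from the hydrocarbon, CO and CO2 pools:
#' `TOC = hc * (S1 + S2) + co * S3_CO + co2 * S3_CO2`, with S-values in mg/g.
#' Defaults follow standard Rock-Eval 6 stoichiometry: 0.083 wt% C per mg/g
#' of hydrocarbons, and the 12/28 and 12/44 carbon mass ratios for CO and CO2
#' (divided by 10 to convert mg/g to wt%).
#'
#' @param hc,co,co2 Conversion factors (wt % C per mg/g).
#' @return A named list.
#' @export
toc_factors <- function(hc = 0.083, co = 12 / 280, co2 = 12 / 440) {
  stopifnot(hc >= 0, co >= 0, co2 >= 0)
  list(hc = hc, co = co, co2 = co2)
}

#' Compute Rock-Eval 6 parameters from a pyrogram
#'
#' Integrates both phases of a pyrogram into the standard Rock-Eval
#' parameter set: S1 (free hydrocarbons, hold-phase FID area), S2 (bound
#' hydrocarbons, ramp-phase FID area), TpkS2 (ramp temperature of maximum
#' yield), S3 CO and S3 CO2 (oxidation-phase areas over the configured
#' windows), TOC (assembled from the carbon pools via [toc_factors()]),
#' HI = 100 * S2 / TOC, OI = 100 * S3_CO2 / TOC, the A1-A4 node areas and
#' the R- and I-indices.
#'
#' @param p A `pyrogram`.
#' @param factors See [toc_factors()].
#' @param s3_co_window,s3_co2_window Oxidation-phase integration windows
#'   (degC, length-2). Defaults integrate the full provided curves.
#'
#' @return A one-row tibble with columns `S1`, `S2`, `S3_CO`, `S3_CO2`,
#'   `TOC`, `TpkS2`, `HI`, `OI`, `A1`-`A4`, `r_index`, `i_index`.
#' @export
#' @examples
#' p <- generate_pyrogram(thermal_composition(c(310, 430), c(15, 15), c(.6, .4)),
#'                        total_s2 = 220)
#' compute_parameters(p)
compute_parameters <- function(p, factors = toc_factors(),
                               s3_co_window = c(-Inf, Inf),
                               s3_co2_window = c(-Inf, Inf)) {
  stopifnot(inherits(p, "pyrogram"))
  hold <- p$pyrolysis[p$pyrolysis$phase == "hold", ]
  ramp <- p$pyrolysis[p$pyrolysis$phase == "ramp", ]
  if (nrow(ramp) < 2) abort("Pyrogram has no ramp phase.")

  s1 <- if (nrow(hold) >= 2) pracma::trapz(hold$time_s, hold$fid_signal) else 0
  s2 <- pracma::trapz(ramp$time_s, ramp$fid_signal)
  tpk <- ramp$temp_c[which.max(ramp$fid_signal)]

  ox <- p$oxidation
  s3_co <- if (nrow(ox) >= 2)
    trapz_window(ox$temp_c, ox$co_signal, s3_co_window[1], s3_co_window[2]) else 0
  s3_co2 <- if (nrow(ox) >= 2)
    trapz_window(ox$temp_c, ox$co2_signal, s3_co2_window[1], s3_co2_window[2]) else 0

  toc <- factors$hc * (s1 + s2) + factors$co * s3_co + factors$co2 * s3_co2
  if (toc <= 0) {
    abort("TOC is zero; HI and OI are undefined.",
          class = "peatsense_undefined_index")
  }

  nodes <- integrate_s2_nodes(p)
  tb(
    S1 = s1, S2 = s2, S3_CO = s3_co, S3_CO2 = s3_co2,
    TOC = toc, TpkS2 = tpk,
    HI = 100 * s2 / toc, OI = 100 * s3_co2 / toc,
    A1 = nodes$A1, A2 = nodes$A2, A3 = nodes$A3, A4 = nodes$A4,
    r_index = r_index(nodes), i_index = i_index(nodes)
  )
}

#' Rock-Eval parameters for a batch of pyrograms
#'
#' @param pyrograms A named list of `pyrogram` objects (names become
#'   `sample_id`).
#' @inheritParams compute_parameters
#' @return A tibble, one row per sample, with `sample_id` plus the
#'   [compute_parameters()] columns.
#' @export
rockeval_table <- function(pyrograms, factors = toc_factors()) {
  stopifnot(is.list(pyrograms), length(pyrograms) > 0)
  ids <- names(pyrograms) %||% as.character(seq_along(pyrograms))
  rows <- lapply(seq_along(pyrograms), function(i) {
    res <- compute_parameters(pyrograms[[i]], factors = factors)
    res$sample_id <- ids[i]
    res
  })
  dplyr::relocate(bind_rows(rows), "sample_id")
}

#' Recompute indices from pre-integrated Rock-Eval parameters
#'
#' When an instrument export already provides the integrated parameters
#' (S1, S2, S3 CO, S3 CO2, TOC, TpkS2, A1-A4), pyrogram processing is
#' skipped and HI, OI and the R-/I-indices are recomputed from the rows.
#'
#' @param params A data frame with columns `S1`, `S2`, `S3_CO`, `S3_CO2`,
#'   `TOC`, `TpkS2`, `A1`, `A2`, `A3`, `A4` (and optionally `sample_id`).
#' @return A tibble with the same rows plus `HI`, `OI`, `r_index`, `i_index`.
#' @export
rockeval_from_parameters <- function(params) {
  needed <- c("S1", "S2", "S3_CO", "S3_CO2", "TOC", "TpkS2",
              "A1", "A2", "A3", "A4")
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing pre-integrated columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  params <- as_tibble(params)
  check_nodes(params)
  if (any(params$TOC <= 0)) {
    abort("TOC is zero; HI and OI are undefined.",
          class = "peatsense_undefined_index")
  }
  params |>
    mutate(
      HI = 100 * .data$S2 / .data$TOC,
      OI = 100 * .data$S3_CO2 / .data$TOC,
      r_index = r_index(params),
      i_index = i_index(params)
    )
}

#' Classify a core segment into a depth layer
#'
#' Assigns each 10 cm segment to one of the depth strata used when comparing
#' thermal-stability indices within cores: the surface peat layer (bottom
#' within the upper 50 cm), peat just below the water table (segment within
#' 50 cm below the water-table depth), and the deepest peat above the
#' underlying clay (within 50 cm of the clay top). A segment matching
#' several rules takes the shallowest applicable label; anything else is
#' `"other"`.
#'
#' @param top_cm,bottom_cm Segment depth interval below the surface (cm),
#'   `top_cm < bottom_cm`. Vectorised.
#' @param water_table_cm Water-table depth (cm below surface).
#' @param clay_top_cm Depth of the underlying clay (cm); segments must not
#'   extend below it.
#'
#' @return A character vector with values `"upper50"`,
#'   `"below_water_table"`, `"deep"` or `"other"`.
#' @export
#' @examples
#' classify_depth_layer(c(0, 60, 250), c(10, 70, 260),
#'                      water_table_cm = 40, clay_top_cm = 300)
classify_depth_layer <- function(top_cm, bottom_cm, water_table_cm,
                                 clay_top_cm) {
  stopifnot(length(top_cm) == length(bottom_cm))
  if (any(top_cm < 0) || any(bottom_cm <= top_cm)) {
    abort("Segments need 0 <= top_cm < bottom_cm.")
  }
  if (any(bottom_cm > clay_top_cm + 1e-9)) {
    abort("Segments must lie above the clay top.")
  }
  out <- rep("other", length(top_cm))
  deep <- top_cm >= clay_top_cm - 50
  bwt <- top_cm >= water_table_cm & bottom_cm <= water_table_cm + 50
  upper <- bottom_cm <= 50
  out[deep] <- "deep"
  out[bwt] <- "below_water_table"
  out[upper] <- "upper50"
  out
}
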