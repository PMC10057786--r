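#' Forest condition classes and their generator defaults
#'
#' The four peat swamp forest condition classes sampled in the study design,
#' with the synthetic-generator parameters attached to each: number of cores,
#' upper-profile labile depletion (the fraction of the thermally labile A1/A2
#' pools lost from the upper 50 cm through enhanced aerobic decomposition),
#' NBR baseline and temporal standard deviation, and above-ground biomass.
#' Depletion and NBR variability are ordered by disturbance severity
#' (CentralForest < ManagedRecovery < DisturbedForest < FireAffected).
#'
#' @return A tibble with one row per class.
#' @export
class_defaults <- function() {
  tibble(
    class = c("CentralForest", "ManagedRecovery", "DisturbedForest",
              "FireAffected"),
    n_sites = c(3L, 2L, 4L, 2L),
    upper_labile_depletion = c(0, 0.30, 0.40, 0.50),
    nbr_baseline = c(0.55, 0.48, 0.38, 0.25),
    nbr_temporal_sd = c(0.03, 0.07, 0.10, 0.14),
    agb_mean_mg_ha = c(320, 280, 244, 120),
    agb_sd_mg_ha = c(25, 25, 20, 15)
  )
}

condition_classes <- function() class_defaults()$class

#' Site scenario for the synthetic core generator
#'
#' Bundles the condition of one sampling location: its class, peat depth,
#' dry-season water-table depth, how depleted the upper 50 cm labile pools
#' are, and the NBR behaviour of its pixels. Defaults for the disturbance
#' parameters come from [class_defaults()].
#'
#' @param condition_class One of the [class_defaults()] classes.
#' @param peat_depth Peat thickness (m), > 0; study cores span 0.5-3.5 m.
#' @param water_table_depth Water-table depth below surface (m); default
#'   0.4 m (dry-season sampling).
#' @param upper_labile_depletion Fraction of labile (A1 + A2) mass removed
#'   from segments in the upper 50 cm, in \[0, 1\]; 0 for pristine sites.
#' @param nbr_baseline,nbr_temporal_sd NBR level and inter-year variability
#'   of the site's pixels, both within \[-1, 1\].
#' @param seed Integer seed controlling all of the site's randomness.
#' @param site_id Site label.
#'
#' @return A list of class `"site_scenario"`.
#' @export
#' @examples
#' site_scenario("CentralForest", peat_depth = 2)
site_scenario <- function(condition_class, peat_depth = 2,
                          water_table_depth = 0.4,
                          upper_labile_depletion = NULL,
                          nbr_baseline = NULL, nbr_temporal_sd = NULL,
                          seed = 1, site_id = "site1") {
  defaults <- class_defaults()
  if (!condition_class %in% defaults$class) {
    abort(paste0("`condition_class` must be one of: ",
                 paste(defaults$class, collapse = ", ")))
  }
  if (peat_depth <= 0) abort("`peat_depth` must be > 0.")
  row <- defaults[defaults$class == condition_class, ]
  depletion <- upper_labile_depletion %||% row$upper_labile_depletion
  baseline <- nbr_baseline %||% row$nbr_baseline
  temporal_sd <- nbr_temporal_sd %||% row$nbr_temporal_sd
  if (depletion < 0 || depletion > 1) {
    abort("`upper_labile_depletion` must lie in [0, 1].")
  }
  if (abs(baseline) > 1) abort("`nbr_baseline` must lie in [-1, 1].")
  if (temporal_sd < 0) abort("`nbr_temporal_sd` must be >= 0.")
  structure(
    list(condition_class = condition_class, peat_depth = peat_depth,
         water_table_depth = water_table_depth,
         upper_labile_depletion = depletion,
         nbr_baseline = baseline, nbr_temporal_sd = temporal_sd,
         seed = as.integer(seed), site_id = site_id),
    class = "site_scenario"
  )
}

# Depth trend of the four thermal pools for pristine peat: the labile pools
# (A1-centred, A2-centred) decline and the refractory pools rise with
# relative depth z in [0, 1]. Placed so a pristine profile drifts from
# R ~ 0.50 / I ~ +0.19 near the surface to R ~ 0.64 / I ~ 0 at depth.
depth_fractions <- function(z) {
  cbind(0.26 - 0.10 * z,
        0.24 - 0.04 * z,
        0.32 + 0.03 * z,
        0.18 + 0.11 * z)
}

# Default component centres: mid-window placements for A1-A3 plus a
# representative > 460 degC centre for the char/recalcitrant pool.
component_centers <- c(310, 370, 430, 500)
component_widths <- c(15, 15, 15, 15)
litter_fractions <- c(0.50, 0.30, 0.14, 0.06)

clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

#' Generate a synthetic peat core with pyrograms
#'
#' Builds the ordered 10 cm segments of one core. Pool fractions follow the
#' pristine depth trend (labile declining, refractory rising) with
#' per-segment jitter; for segments in the upper 50 cm the labile pools are
#' additionally depleted by the scenario's `upper_labile_depletion`, which
#' removes mass (lowering S2 and TOC) rather than merely reshuffling it --
#' the thermal signature of enhanced surface decomposition. Segment dry
#' masses are drawn so bulk density centres on 0.10 g cm^-3 (sd 0.008).
#' Rock-Eval sub-samples are selected per `measure`: either every segment,
#' or (default) all upper-50 cm segments plus every second deeper segment
#' and the basal one, mimicking measurement on selected sub-samples with
#' TOC interpolation in between.
#'
#' @param scenario A [site_scenario()].
#' @param program A [temp_program()].
#' @param base_s2 Mean undepleted S2 yield (mg HC/g); 220 gives TOC near
#'   55 wt % and HI near 400 under the default TOC factors.
#' @param bd_mean,bd_sd Bulk-density distribution (g cm^-3).
#' @param s2_lognoise Lognormal sd of per-segment S2 variability.
#' @param fraction_jitter Gaussian sd added to pool fractions per segment.
#' @param dry_mass_fraction Mean dry:wet mass ratio of fresh peat.
#' @param detector_noise_sd FID detector noise (signal units per second).
#' @param measure `"stratified"` (default) or `"all"` segments analysed.
#' @param include_litter Also generate a surface leaf-litter sample
#'   (labelled layer `"litter"`, no mass or depth).
#'
#' @return An object of class `"peat_core"`: `$segments` (tibble),
#'   `$pyrograms` (named list over measured samples), `$scenario`.
#' @export
#' @examples
#' core <- generate_core(site_scenario("CentralForest", peat_depth = 0.5))
#' nrow(core$segments)  # 5 segments of 10 cm
generate_core <- function(scenario, program = temp_program(),
                          base_s2 = 220, bd_mean = 0.10, bd_sd = 0.008,
                          s2_lognoise = 0.05, fraction_jitter = 0.012,
                          dry_mass_fraction = 0.12,
                          detector_noise_sd = 0.005,
                          measure = c("stratified", "all"),
                          include_litter = TRUE) {
  stopifnot(inherits(scenario, "site_scenario"))
  measure <- match.arg(measure)
  if (scenario$peat_depth <= 0) abort("`peat_depth` must be > 0.")
  depth_cm <- round(scenario$peat_depth * 10) * 10
  n_seg <- depth_cm / 10
  vol <- corer_volume_cm3()

  withr::with_seed(scenario$seed, {
    top <- (seq_len(n_seg) - 1) * 10
    bottom <- top + 10
    z <- ((top + bottom) / 2) / depth_cm

    frac <- depth_fractions(z) +
      matrix(rnorm(4 * n_seg, 0, fraction_jitter), ncol = 4)
    frac <- clamp(frac, 0.01, 1)
    frac <- frac / rowSums(frac)

    upper <- bottom <= 50
    depl <- ifelse(upper, scenario$upper_labile_depletion, 0)
    labile_share <- frac[, 1] + frac[, 2]
    mass_mult <- 1 - depl * labile_share     # HC mass retained
    ox_mult <- 1 - 0.5 * depl * labile_share # oxidation pools less affected
    frac_dep <- frac
    frac_dep[, 1:2] <- frac[, 1:2] * (1 - depl)
    frac_dep <- frac_dep / rowSums(frac_dep)

    s2_base <- base_s2 * exp(rnorm(n_seg, 0, s2_lognoise))
    s2 <- s2_base * mass_mult
    dry_g <- clamp(rnorm(n_seg, bd_mean, bd_sd), 0.02, Inf) * vol
    wet_g <- dry_g / clamp(rnorm(n_seg, dry_mass_fraction, 0.01), 0.05, 0.5)

    measured <- if (measure == "all") rep(TRUE, n_seg) else {
      upper | (seq_len(n_seg) > 5 & (seq_len(n_seg) - 6) %% 2 == 0) |
        seq_len(n_seg) == n_seg
    }

    sample_id <- sprintf("%s_%03d", scenario$site_id, top)
    segments <- tibble(
      sample_id = sample_id, site_id = scenario$site_id,
      class = scenario$condition_class,
      top_cm = top, bottom_cm = bottom,
      wet_g = wet_g, dry_g = dry_g, measured = measured,
      s2_mg_g = s2
    )

    pyrograms <- list()
    for (i in which(measured)) {
      comp <- thermal_composition(component_centers, component_widths,
                                  frac_dep[i, ])
      pyrograms[[sample_id[i]]] <- generate_pyrogram(
        comp, total_s2 = s2[i], program = program,
        noise_sd = detector_noise_sd,
        s1 = 0.02 * s2[i],
        oxidation = list(co_mg = 0.32 * s2_base[i] * ox_mult[i],
                         co2_mg = 5.6 * s2_base[i] * ox_mult[i],
                         co_center = 450, co_sigma = 60,
                         co2_center = 480, co2_sigma = 70),
        sample_id = sample_id[i]
      )
    }

    if (include_litter) {
      lid <- paste0(scenario$site_id, "_litter")
      lf <- clamp(litter_fractions + rnorm(4, 0, fraction_jitter), 0.01, 1)
      lf <- lf / sum(lf)
      ls2 <- 1.1 * base_s2 * exp(rnorm(1, 0, s2_lognoise))
      pyrograms[[lid]] <- generate_pyrogram(
        thermal_composition(component_centers, component_widths, lf),
        total_s2 = ls2, program = program, noise_sd = detector_noise_sd,
        s1 = 0.02 * ls2,
        oxidation = list(co_mg = 0.32 * ls2, co2_mg = 5.6 * ls2,
                         co_center = 450, co_sigma = 60,
                         co2_center = 480, co2_sigma = 70),
        sample_id = lid
      )
    }

    structure(list(segments = segments, pyrograms = pyrograms,
                   scenario = scenario),
              class = "peat_core")
  })
}

#' @export
print.peat_core <- function(x, ...) {
  cat("<peat_core> ", x$scenario$site_id, " (", x$scenario$condition_class,
      "): ", nrow(x$segments), " segments, ", length(x$pyrograms),
      " pyrograms\n", sep = "")
  invisible(x)
}

#' Study configuration for the synthetic generator
#'
#' Defines the shape of a generated study: cores per condition class
#' (default 3/2/4/2 as in the field design), acquisition years, raster grid,
#' peat-depth range and the disturbance contrast switch. With
#' `disturbance_contrast = FALSE` every class takes the CentralForest
#' parameters (no depletion, identical NBR behaviour), giving a null dataset
#' for calibration.
#'
#' @param n_sites Named integer vector of cores per class.
#' @param years Acquisition years (>= 2 for a temporal sd to exist).
#' @param grid_nrow,grid_ncol,res_m Raster grid shape and cell size (m).
#' @param depth_range_m Range peat depths are drawn from (uniform).
#' @param water_table_m Water-table depth below surface (m).
#' @param disturbance_contrast Logical; see above.
#' @param class_params Per-class parameter tibble, see [class_defaults()].
#' @param pixel_jitter_sd Spatial sd of the per-pixel NBR baseline.
#' @param reflectance_sum NIR + SWIR2 total used to back out band values
#'   from NBR.
#' @param measure,include_litter Passed to [generate_core()].
#' @param base_s2,bd_mean,bd_sd Passed to [generate_core()].
#'
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_sites = c(CentralForest = 3, ManagedRecovery = 2,
                                     DisturbedForest = 4, FireAffected = 2),
                         years = c(1989, 1995, 2001, 2010, 2019),
                         grid_nrow = 24, grid_ncol = 24, res_m = 30,
                         depth_range_m = c(0.5, 3.5),
                         water_table_m = 0.4,
                         disturbance_contrast = TRUE,
                         class_params = class_defaults(),
                         pixel_jitter_sd = 0.02,
                         reflectance_sum = 0.5,
                         measure = "stratified", include_litter = TRUE,
                         base_s2 = 220, bd_mean = 0.10, bd_sd = 0.008) {
  if (sum(n_sites) < 1) abort("Need at least one site.")
  if (length(years) < 2) {
    abort("Need at least two years for a temporal sd to exist.")
  }
  stopifnot(all(names(n_sites) %in% class_params$class),
            depth_range_m[1] > 0, diff(depth_range_m) >= 0,
            reflectance_sum > 0, reflectance_sum <= 1)
  structure(
    list(n_sites = n_sites, years = as.integer(years),
         grid_nrow = grid_nrow, grid_ncol = grid_ncol, res_m = res_m,
         depth_range_m = depth_range_m, water_table_m = water_table_m,
         disturbance_contrast = disturbance_contrast,
         class_params = class_params,
         pixel_jitter_sd = pixel_jitter_sd,
         reflectance_sum = reflectance_sum,
         measure = measure, include_litter = include_litter,
         base_s2 = base_s2, bd_mean = bd_mean, bd_sd = bd_sd),
    class = "study_config"
  )
}

#' Generate a complete synthetic study dataset
#'
#' Produces everything the analysis pipeline consumes: one [generate_core()]
#' result per site, a site table with jittered-grid coordinates and
#' above-ground biomass, a multi-year [scene_stack()] whose pixels carry
#' each class's NBR baseline and temporal variability (pixels take the class
#' of their nearest site), and river/canal polylines. All randomness flows
#' from the single `seed`; a fixed seed gives bit-identical output.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return An object of class `"study_dataset"`: `$cores` (named list),
#'   `$segments` (combined tibble), `$sites`, `$stack`, `$river`, `$canals`,
#'   `$config`, `$seed`.
#' @export
#' @examples
#' study <- generate_study(study_config(grid_nrow = 12, grid_ncol = 12),
#'                         seed = 1)
#' length(study$cores)  # 11
generate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  params <- config$class_params
  if (!config$disturbance_contrast) {
    cf <- params[params$class == "CentralForest", ]
    params$upper_labile_depletion <- cf$upper_labile_depletion
    params$nbr_baseline <- cf$nbr_baseline
    params$nbr_temporal_sd <- cf$nbr_temporal_sd
  }

  withr::with_seed(as.integer(seed), {
    classes <- rep(names(config$n_sites), config$n_sites)
    n <- length(classes)
    site_id <- sprintf("P%02d", seq_len(n))

    # jittered grid of site coordinates inside the raster extent
    width <- config$grid_ncol * config$res_m
    height <- config$grid_nrow * config$res_m
    gx <- ceiling(sqrt(n))
    gy <- ceiling(n / gx)
    cell_w <- width / gx
    cell_h <- height / gy
    ord <- sample(n)  # scatter classes across the grid
    cx <- ((ord - 1) %% gx + 0.5) * cell_w
    cy <- ((ord - 1) %/% gx + 0.5) * cell_h
    x <- cx + runif(n, -0.25, 0.25) * cell_w
    y <- cy + runif(n, -0.25, 0.25) * cell_h
    if (anyDuplicated(cbind(x, y)) > 0) {
      abort("Overlapping site coordinates; change the seed or extent.")
    }

    par_of <- function(cls, col) params[[col]][match(cls, params$class)]
    depth <- round(runif(n, config$depth_range_m[1], config$depth_range_m[2]),
                   1)
    agb <- clamp(rnorm(n, par_of(classes, "agb_mean_mg_ha"),
                       par_of(classes, "agb_sd_mg_ha")), 0, Inf)
    site_seeds <- sample.int(.Machine$integer.max - 1, n)

    sites <- tibble(
      site_id = site_id, class = classes, x = x, y = y,
      agb_mg_ha = agb, peat_depth_m = depth,
      water_table_cm = config$water_table_m * 100
    )

    cores <- lapply(seq_len(n), function(i) {
      sc <- site_scenario(
        classes[i], peat_depth = depth[i],
        water_table_depth = config$water_table_m,
        upper_labile_depletion = par_of(classes[i], "upper_labile_depletion"),
        nbr_baseline = par_of(classes[i], "nbr_baseline"),
        nbr_temporal_sd = par_of(classes[i], "nbr_temporal_sd"),
        seed = site_seeds[i], site_id = site_id[i]
      )
      generate_core(sc, measure = config$measure,
                    include_litter = config$include_litter,
                    base_s2 = config$base_s2, bd_mean = config$bd_mean,
                    bd_sd = config$bd_sd)
    })
    names(cores) <- site_id

    # rasters: each pixel inherits the NBR behaviour of its nearest site
    nrow_g <- config$grid_nrow
    ncol_g <- config$grid_ncol
    px_x <- (seq_len(ncol_g) - 0.5) * config$res_m
    px_y <- height - (seq_len(nrow_g) - 0.5) * config$res_m
    xg <- matrix(px_x, nrow_g, ncol_g, byrow = TRUE)
    yg <- matrix(px_y, nrow_g, ncol_g)
    nearest <- matrix(0L, nrow_g, ncol_g)
    best <- matrix(Inf, nrow_g, ncol_g)
    for (i in seq_len(n)) {
      d2 <- (xg - x[i])^2 + (yg - y[i])^2
      hit <- d2 < best
      nearest[hit] <- i
      best[hit] <- d2[hit]
    }
    base_px <- matrix(par_of(classes[nearest], "nbr_baseline"),
                      nrow_g, ncol_g) +
      matrix(rnorm(nrow_g * ncol_g, 0, config$pixel_jitter_sd),
             nrow_g, ncol_g)
    sd_px <- matrix(par_of(classes[nearest], "nbr_temporal_sd"),
                    nrow_g, ncol_g)
    half <- config$reflectance_sum / 2
    nir <- list(); swir2 <- list()
    for (t in seq_along(config$years)) {
      n_t <- clamp(base_px + matrix(rnorm(nrow_g * ncol_g), nrow_g, ncol_g) *
                     sd_px, -0.95, 0.95)
      nir[[t]] <- half * (1 + n_t)
      swir2[[t]] <- half * (1 - n_t)
    }
    stack <- scene_stack(config$years, nir, swir2, xmin = 0, ymax = height,
                         res_m = config$res_m, crs_units = "m")

    # river meanders through the extent; canals run in from one edge
    ry <- seq(0, height, length.out = 41)
    river <- list(cbind(width * (0.5 + 0.15 * sin(ry / height * 3 * pi)), ry))
    canals <- list(
      cbind(seq(0, 0.45 * width, length.out = 12),
            height * (0.22 + 0.05 * sin(seq(0, 2 * pi, length.out = 12)))),
      cbind(seq(0, 0.4 * width, length.out = 10),
            height * (0.72 + 0.04 * cos(seq(0, 2 * pi, length.out = 10))))
    )
    attr(river, "crs_units") <- "m"
    attr(canals, "crs_units") <- "m"

    segments <- bind_rows(lapply(cores, function(co) co$segments))

    structure(
      list(cores = cores, segments = segments, sites = sites, stack = stack,
           river = river, canals = canals, config = config,
           seed = as.integer(seed)),
      class = "study_dataset"
    )
  })
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", nrow(x$sites), " sites, ",
      nrow(x$segments), " segments, ",
      length(x$stack$years), "-year stack (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a study dataset to plain-text files
#'
#' Persists a [generate_study()] result: `cores.csv`, `sites.csv`, one
#' pyrogram CSV per analysed sample under `pyrograms/`, per-year NIR and
#' SWIR-2 ASCII grids, and `river.geojson` / `canals.geojson`.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(file.path(dir, "pyrograms"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(
    select(study$segments, "site_id", "class", segment_top_cm = "top_cm",
           segment_bottom_cm = "bottom_cm", "wet_g", "dry_g",
           "sample_id", "measured"),
    file.path(dir, "cores.csv"), progress = FALSE)
  readr::write_csv(study$sites, file.path(dir, "sites.csv"), progress = FALSE)
  for (co in study$cores) {
    for (id in names(co$pyrograms)) {
      write_pyrogram(co$pyrograms[[id]],
                     file.path(dir, "pyrograms", paste0(id, ".csv")))
    }
  }
  st <- study$stack
  ymin <- st$ymax - nrow(st$nir[[1]]) * st$res_m
  for (t in seq_along(st$years)) {
    write_ascii_grid(st$nir[[t]],
                     file.path(dir, sprintf("nir_%d.asc", st$years[t])),
                     xmin = st$xmin, ymin = ymin, res_m = st$res_m)
    write_ascii_grid(st$swir2[[t]],
                     file.path(dir, sprintf("swir2_%d.asc", st$years[t])),
                     xmin = st$xmin, ymin = ymin, res_m = st$res_m)
  }
  write_geojson_lines(study$river, file.path(dir, "river.geojson"))
  write_geojson_lines(study$canals, file.path(dir, "canals.geojson"))
  invisible(dir)
}
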