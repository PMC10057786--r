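#' Multi-year two-band reflectance stack
#'
#' A lightweight co-registered raster stack: per-year NIR and SWIR-2
#' surface-reflectance matrices on a shared grid with a simple
#' north-up geotransform (projected coordinates in metres). Matrix rows run
#' north to south, columns west to east; the cell (1, 1) has its upper-left
#' corner at (`xmin`, `ymax`).
#'
#' @param years Integer vector of acquisition years.
#' @param nir,swir2 Lists (one matrix per year) of reflectances in \[0, 1\];
#'   `NA` is nodata. All matrices must share dimensions.
#' @param xmin,ymax Upper-left corner of the grid (m).
#' @param res_m Square cell size (m).
#' @param crs_units `"m"` for projected metre coordinates (required by
#'   distance computations) or `"deg"`.
#'
#' @return An object of class `"scene_stack"`.
#' @export
scene_stack <- function(years, nir, swir2, xmin = 0, ymax = NULL, res_m = 30,
                        crs_units = "m") {
  stopifnot(length(years) >= 1, length(nir) == length(years),
            length(swir2) == length(years), res_m > 0)
  dims <- dim(nir[[1]])
  for (m in c(nir, swir2)) {
    if (!is.matrix(m) || !identical(dim(m), dims)) {
      abort("All band matrices must share the same grid shape.")
    }
    if (any(m < 0 | m > 1, na.rm = TRUE)) {
      abort("Reflectances must lie in [0, 1] (or be NA).")
    }
  }
  if (is.null(ymax)) ymax <- dims[1] * res_m
  structure(
    list(years = as.integer(years), nir = nir, swir2 = swir2,
         xmin = xmin, ymax = ymax, res_m = res_m, crs_units = crs_units),
    class = "scene_stack"
  )
}

#' @export
print.scene_stack <- function(x, ...) {
  d <- dim(x$nir[[1]])
  cat("<scene_stack> ", length(x$years), " years (",
      paste(x$years, collapse = ", "), ")\n", sep = "")
  cat("  grid: ", d[1], " x ", d[2], " cells, ", x$res_m, " ",
      x$crs_units, " resolution\n", sep = "")
  invisible(x)
}

#' Normalised burn ratio
#'
#' `NBR = (NIR - SWIR2) / (NIR + SWIR2)`, ranging between 1 and -1; low
#' values indicate sparse or absent vegetation, high values dense healthy
#' vegetation. Pixels where both bands are zero (or either is nodata) are
#' returned as `NA`.
#'
#' @param nir,swir2 Reflectances (vectors or matrices of equal shape), >= 0.
#' @return NBR values with the shape of the inputs.
#' @export
#' @examples
#' nbr(0.5, 0.1)  # 0.667
nbr <- function(nir, swir2) {
  if (any(nir < 0, na.rm = TRUE) || any(swir2 < 0, na.rm = TRUE)) {
    abort("Reflectances must be >= 0.")
  }
  total <- nir + swir2
  out <- (nir - swir2) / total
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

#' NBR time-series statistics for a scene stack
#'
#' Computes the per-year NBR rasters and per-pixel descriptive statistics
#' over the stack: the temporal mean (a recent view of vegetation cover and
#' condition) and the sample (n-1) standard deviation (a measure of pixel
#' variability over time; high values flag repeated disturbance). Nodata is
#' propagated: a pixel's statistics use its valid years only, and pixels
#' with fewer than two valid years get `NA` sd.
#'
#' @param stack A [scene_stack()] with at least two years.
#' @return An object of class `"nbr_products"`: list with `years`,
#'   `nbr` (list of matrices), `nbr_mean`, `nbr_sd`, `n_valid`, and the
#'   grid geometry fields of the stack.
#' @export
stack_stats <- function(stack) {
  stopifnot(inherits(stack, "scene_stack"))
  if (length(stack$years) < 2) {
    abort("Need at least two years to compute a temporal standard deviation.")
  }
  layers <- lapply(seq_along(stack$years), function(i) {
    nbr(stack$nir[[i]], stack$swir2[[i]])
  })
  names(layers) <- stack$years
  arr <- array(unlist(layers), dim = c(dim(layers[[1]]), length(layers)))
  n_valid <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  nbr_mean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nbr_mean[n_valid == 0] <- NA_real_
  nbr_sd <- apply(arr, c(1, 2), sd, na.rm = TRUE)
  nbr_sd[n_valid < 2] <- NA_real_
  structure(
    list(years = stack$years, nbr = layers, nbr_mean = nbr_mean,
         nbr_sd = nbr_sd, n_valid = n_valid,
         xmin = stack$xmin, ymax = stack$ymax, res_m = stack$res_m,
         crs_units = stack$crs_units),
    class = "nbr_products"
  )
}

#' @export
print.nbr_products <- function(x, ...) {
  cat("<nbr_products> ", length(x$years), " years; mean NBR ",
      signif(mean(x$nbr_mean, na.rm = TRUE), 3), ", mean temporal sd ",
      signif(mean(x$nbr_sd, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk normality check of NBR pixel time series
#'
#' Samples pixel time series from the NBR stack (seeded, without
#' replacement) and applies the Shapiro-Wilk test to each, supporting the
#' use of the temporal sd raster as a variability measure. Constant series
#' have an undefined test statistic and are flagged rather than dropped.
#'
#' @param stack A [scene_stack()].
#' @param sample_size Number of pixels to sample.
#' @param seed Integer seed for the pixel sample.
#' @return A tibble with `row`, `col`, `n`, `W`, `p_value`, `undefined`,
#'   plus an attribute `frac_rejected` (fraction of defined tests with
#'   p < 0.05).
#' @export
normality_check <- function(stack, sample_size = 100, seed = 1) {
  stopifnot(inherits(stack, "scene_stack"), sample_size >= 1)
  prod <- stack_stats(stack)
  ny <- length(prod$years)
  if (ny < 3 || ny > 5000) {
    abort("Shapiro-Wilk needs between 3 and 5000 observations per series.")
  }
  ok <- which(prod$n_valid >= 3, arr.ind = TRUE)
  if (nrow(ok) == 0) abort("No pixels with >= 3 valid years.")
  take <- withr::with_seed(seed,
    ok[sample(nrow(ok), min(sample_size, nrow(ok))), , drop = FALSE])
  res <- lapply(seq_len(nrow(take)), function(k) {
    series <- vapply(prod$nbr, function(m) m[take[k, 1], take[k, 2]],
                     numeric(1))
    series <- series[!is.na(series)]
    if (length(unique(series)) == 1) {
      tibble(row = take[k, 1], col = take[k, 2], n = length(series),
             W = NA_real_, p_value = NA_real_, undefined = TRUE)
    } else {
      sw <- stats::shapiro.test(series)
      tibble(row = take[k, 1], col = take[k, 2], n = length(series),
             W = unname(sw$statistic), p_value = sw$p.value, undefined = FALSE)
    }
  })
  out <- bind_rows(res)
  attr(out, "frac_rejected") <- mean(out$p_value < 0.05, na.rm = TRUE)
  out
}

# World -> grid index for the stack geometry (nearest pixel = containing cell).
cell_index <- function(geo, x, y) {
  col <- floor((x - geo$xmin) / geo$res_m) + 1
  row <- floor((geo$ymax - y) / geo$res_m) + 1
  list(row = row, col = col)
}

#' Extract raster values at site coordinates
#'
#' Nearest-pixel (containing-cell) extraction of one or more product layers
#' at point locations; no interpolation is applied.
#'
#' @param products An [stack_stats()] result (or any list with matrices plus
#'   `xmin`, `ymax`, `res_m` geometry fields).
#' @param sites A data frame with `site_id`, `x`, `y` (same projected CRS as
#'   the rasters).
#' @param layers Character names of matrix layers to extract (default
#'   `c("nbr_mean", "nbr_sd")`).
#' @return `sites` with one extracted column per layer.
#' @export
extract_at_sites <- function(products, sites,
                             layers = c("nbr_mean", "nbr_sd")) {
  stopifnot(is.data.frame(sites), all(c("site_id", "x", "y") %in% names(sites)))
  dims <- dim(products[[layers[1]]])
  idx <- cell_index(products, sites$x, sites$y)
  bad <- idx$row < 1 | idx$row > dims[1] | idx$col < 1 | idx$col > dims[2]
  if (any(bad)) {
    abort(paste0("Site(s) outside raster bounds: ",
                 paste(sites$site_id[bad], collapse = ", ")))
  }
  out <- as_tibble(sites)
  for (ly in layers) {
    m <- products[[ly]]
    if (!is.matrix(m)) abort(paste0("Layer `", ly, "` is not a matrix."))
    out[[ly]] <- m[cbind(idx$row, idx$col)]
  }
  out
}

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format (NCOLS/NROWS/XLLCORNER/... header plus
#' rows of values from north to south), used to persist NBR product layers.
#'
#' @param m Matrix (rows north to south).
#' @param path File path.
#' @param xmin,ymin Lower-left corner (m).
#' @param res_m Cell size (m).
#' @param nodata Nodata sentinel written in place of `NA`.
#' @return `read_ascii_grid()` returns a list with `m`, `xmin`, `ymin`,
#'   `res_m`; `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(m, path, xmin = 0, ymin = 0, res_m = 30,
                             nodata = -9999) {
  stopifnot(is.matrix(m))
  header <- c(
    paste("NCOLS", ncol(m)), paste("NROWS", nrow(m)),
    paste("XLLCORNER", format(xmin, scientific = FALSE)),
    paste("YLLCORNER", format(ymin, scientific = FALSE)),
    paste("CELLSIZE", format(res_m, scientific = FALSE)),
    paste("NODATA_VALUE", nodata)
  )
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- lines[1:6]
  vals <- strsplit(trimws(header), "\\s+")
  key <- toupper(vapply(vals, `[`, character(1), 1))
  num <- as.numeric(vapply(vals, `[`, character(1), 2))
  names(num) <- key
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  m[m == num[["NODATA_VALUE"]]] <- NA_real_
  list(m = m, xmin = num[["XLLCORNER"]], ymin = num[["YLLCORNER"]],
       res_m = num[["CELLSIZE"]])
}
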