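#' Thermal components of a synthetic S2 pyrogram
#'
#' A thermal component represents one organic-matter pool cracking over a
#' Gaussian temperature window during pyrolysis. Four pools are conventionally
#' distinguished in soils and peats: thermally labile fresh plant matter,
#' lignin/cellulose, humified macromolecules, and mature recalcitrant
#' matter or char; these underlie the A1-A4 node areas of the S2 pyrogram.
#'
#' @param center_temp Peak cracking temperature (degC). Must lie within the
#'   pyrolysis ramp, 200-650 degC.
#' @param width Gaussian sigma (degC), > 0.
#' @param mass_fraction Fraction of the total S2 mass in this pool, in
#'   \[0, 1\]. The fractions of a composition must sum to 1.
#'
#' @return A one-row tibble with columns `center_temp`, `width`,
#'   `mass_fraction`. Rows can be bound into a composition with
#'   [dplyr::bind_rows()] or built directly with [thermal_composition()].
#' @export
#' @examples
#' thermal_component(310, 15, 1)
thermal_component <- function(center_temp, width, mass_fraction) {
  stopifnot(is.numeric(center_temp), is.numeric(width), is.numeric(mass_fraction))
  if (width <= 0) abort("`width` must be > 0.")
  if (mass_fraction < 0 || mass_fraction > 1) {
    abort("`mass_fraction` must lie in [0, 1].")
  }
  tb(center_temp = center_temp, width = width, mass_fraction = mass_fraction)
}

#' @param centers,widths,fractions Parallel numeric vectors describing several
#'   components at once.
#' @rdname thermal_component
#' @export
thermal_composition <- function(centers, widths, fractions) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(fractions))
  comp <- tb(center_temp = as.numeric(centers),
             width = as.numeric(widths),
             mass_fraction = as.numeric(fractions))
  validate_composition(comp)
  comp
}

validate_composition <- function(composition) {
  if (is.null(composition) || nrow(composition) == 0) {
    abort("`composition` must contain at least one thermal component.")
  }
  needed <- c("center_temp", "width", "mass_fraction")
  if (!all(needed %in% names(composition))) {
    abort("`composition` needs columns center_temp, width, mass_fraction.")
  }
  if (any(composition$width <= 0)) abort("Component widths must be > 0.")
  if (any(composition$center_temp < 200 | composition$center_temp > 650)) {
    abort("Component centers must lie within the pyrolysis ramp [200, 650] degC.")
  }
  if (abs(sum(composition$mass_fraction) - 1) > 1e-9) {
    abort("Component mass fractions must sum to 1 (within 1e-9).")
  }
  invisible(composition)
}

new_pyrogram <- function(pyrolysis, oxidation, sample_id = NA_character_) {
  stopifnot(is.data.frame(pyrolysis), is.data.frame(oxidation))
  if (nrow(pyrolysis) == 0) abort("Pyrolysis curve is empty.")
  if (any(diff(pyrolysis$time_s) <= 0)) {
    abort("Pyrolysis time axis must be strictly ascending.")
  }
  if (any(diff(pyrolysis$temp_c) < 0)) {
    abort("Pyrolysis temperatures must be non-decreasing.")
  }
  if (nrow(oxidation) > 0 && any(diff(oxidation$temp_c) <= 0)) {
    abort("Oxidation temperatures must be strictly ascending.")
  }
  if (!all(is.finite(pyrolysis$fid_signal))) abort("FID signal must be finite.")
  structure(
    list(pyrolysis = as_tibble(pyrolysis), oxidation = as_tibble(oxidation),
         sample_id = sample_id),
    class = "pyrogram"
  )
}

#' @export
print.pyrogram <- function(x, ...) {
  ramp <- x$pyrolysis[x$pyrolysis$phase == "ramp", ]
  cat("<pyrogram>", if (!is.na(x$sample_id)) x$sample_id else "", "\n")
  cat("  pyrolysis: ", nrow(x$pyrolysis), " samples, ",
      min(x$pyrolysis$temp_c), "-", max(x$pyrolysis$temp_c), " degC\n", sep = "")
  cat("  oxidation: ", nrow(x$oxidation), " samples\n", sep = "")
  cat("  approx S2: ", signif(pracma::trapz(ramp$time_s, ramp$fid_signal), 4),
      " mg HC/g\n", sep = "")
  invisible(x)
}

#' Generate a synthetic Rock-Eval pyrogram
#'
#' Builds a two-phase synthetic pyrogram: an FID curve over the isothermal
#' hold (yielding S1) and the pyrolysis ramp (yielding S2 as a Gaussian
#' mixture over temperature), plus single-Gaussian CO and CO2 curves over the
#' oxidation ramp. The FID signal is expressed per second along a time axis
#' (the hold phase sits at constant temperature, so temperature alone cannot
#' index it); trapezoid integration over time recovers the S1 and S2 masses.
#'
#' @param composition Tibble of thermal components (see
#'   [thermal_composition()]); mass fractions must sum to 1.
#' @param total_s2 Total S2 yield (mg HC/g). Zero gives a flat zero curve.
#' @param program A [temp_program()].
#' @param noise_sd Additive Gaussian detector noise (signal units per second
#'   on the FID curve), >= 0.
#' @param seed Integer seed for the noise; ignored when `noise_sd = 0`.
#' @param s1 Free-hydrocarbon yield released during the hold (mg HC/g).
#' @param oxidation List with elements `co_mg`, `co2_mg` (masses, mg/g) and
#'   `co_center`, `co_sigma`, `co2_center`, `co2_sigma` (degC) describing the
#'   oxidation-phase CO/CO2 release curves.
#' @param sample_id Optional sample label.
#'
#' @return A `pyrogram` object: `$pyrolysis` (time_s, temp_c, phase,
#'   fid_signal) and `$oxidation` (temp_c, co_signal, co2_signal).
#' @export
#' @examples
#' p <- generate_pyrogram(thermal_composition(310, 15, 1), total_s2 = 100)
#' integrate_s2_nodes(p)
generate_pyrogram <- function(composition, total_s2,
                              program = temp_program(),
                              noise_sd = 0, seed = NULL,
                              s1 = 0.02 * total_s2,
                              oxidation = list(co_mg = 0.32 * total_s2,
                                               co2_mg = 5.6 * total_s2,
                                               co_center = 450, co_sigma = 60,
                                               co2_center = 480, co2_sigma = 70),
                              sample_id = NA_character_) {
  validate_composition(composition)
  stopifnot(is.numeric(total_s2), total_s2 >= 0, noise_sd >= 0, s1 >= 0)

  rate_c_s <- program$ramp_rate_c_min / 60
  hold_s <- program$hold_min * 60
  dt <- program$ramp_step_c / rate_c_s

  hold_time <- seq(0, hold_s - dt, by = dt)
  ramp_temp <- seq(program$hold_temp_c, program$ramp_end_c,
                   by = program$ramp_step_c)
  ramp_time <- hold_s + (ramp_temp - program$hold_temp_c) / rate_c_s

  # mixture density over temperature, converted to a per-second signal
  mix <- rep(0, length(ramp_temp))
  for (i in seq_len(nrow(composition))) {
    mix <- mix + composition$mass_fraction[i] *
      dnorm(ramp_temp, composition$center_temp[i], composition$width[i])
  }
  fid_ramp <- total_s2 * mix * rate_c_s
  # constant emission whose trapezoid over the sampled hold span is exactly s1
  hold_span <- max(hold_time) - min(hold_time)
  fid_hold <- rep(if (hold_span > 0) s1 / hold_span else 0, length(hold_time))

  pyr <- tb(
    time_s = c(hold_time, ramp_time),
    temp_c = c(rep(program$hold_temp_c, length(hold_time)), ramp_temp),
    phase = c(rep("hold", length(hold_time)), rep("ramp", length(ramp_temp))),
    fid_signal = c(fid_hold, fid_ramp)
  )
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(nrow(pyr), 0, noise_sd) else
      withr::with_seed(seed, rnorm(nrow(pyr), 0, noise_sd))
    pyr$fid_signal <- pyr$fid_signal + noise
  }

  ox_temp <- seq(program$oxid_start_c, program$oxid_end_c,
                 by = program$oxid_step_c)
  ox <- tb(
    temp_c = ox_temp,
    co_signal = oxidation$co_mg * dnorm(ox_temp, oxidation$co_center,
                                        oxidation$co_sigma),
    co2_signal = oxidation$co2_mg * dnorm(ox_temp, oxidation$co2_center,
                                          oxidation$co2_sigma)
  )
  new_pyrogram(pyr, ox, sample_id = sample_id)
}

#' Read and write pyrogram CSV files
#'
#' Pyrograms are serialised as one long-format CSV per sample with columns
#' `phase` (hold/ramp/oxidation), `time_s`, `temp_c`, `fid_signal`,
#' `co_signal`, `co2_signal`; columns not applicable to a phase are empty.
#'
#' @param p A `pyrogram`.
#' @param path File path.
#' @return `read_pyrogram()` returns a `pyrogram`; `write_pyrogram()` returns
#'   `path` invisibly.
#' @export
write_pyrogram <- function(p, path) {
  stopifnot(inherits(p, "pyrogram"))
  long <- bind_rows(
    tibble(phase = p$pyrolysis$phase, time_s = p$pyrolysis$time_s,
           temp_c = p$pyrolysis$temp_c, fid_signal = p$pyrolysis$fid_signal,
           co_signal = NA_real_, co2_signal = NA_real_),
    tibble(phase = "oxidation", time_s = NA_real_, temp_c = p$oxidation$temp_c,
           fid_signal = NA_real_, co_signal = p$oxidation$co_signal,
           co2_signal = p$oxidation$co2_signal)
  )
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pyrogram
#' @param sample_id Optional sample label attached on read.
#' @export
read_pyrogram <- function(path, sample_id = NA_character_) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pyr <- long[long$phase %in% c("hold", "ramp"),
              c("time_s", "temp_c", "phase", "fid_signal")]
  ox <- long[long$phase == "oxidation", c("temp_c", "co_signal", "co2_signal")]
  new_pyrogram(as_tibble(pyr), as_tibble(ox), sample_id = sample_id)
}
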