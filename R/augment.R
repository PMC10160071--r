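#' Augmentation configuration
#'
#' The five-transform recipe expands a cohort six-fold: each original spectrum
#' is kept and joined by (1) small additive Gaussian noise with
#' `sd = max(spectrum) / noise_small_divisor`, (2) additive Gaussian noise
#' with `sd = noise_unit_sd`, (3) a wavenumber shift drawn uniformly from
#' `[-shift_halfwidth, shift_halfwidth]` (simulating wavelength-calibration
#' inaccuracy), (4) small noise plus a shift, (5) unit noise plus a shift.
#'
#' @param noise_small_divisor Divisor of the per-spectrum maximum intensity
#'   for the small-noise SD (default 1000).
#' @param noise_unit_sd SD of the large additive noise (default 1).
#' @param shift_halfwidth Half-width of the uniform shift, cm^-1 (default 5).
#' @param seed Integer seed; each (spectrum, variant) transform draws from its
#'   own stream derived from this seed, so augmentation is order-independent.
#' @return An `augment_config` list.
#' @export
augment_config <- function(noise_small_divisor = 1000, noise_unit_sd = 1,
                           shift_halfwidth = 5, seed = 1L) {
  if (noise_small_divisor <= 0) stop("`noise_small_divisor` must be > 0", call. = FALSE)
  if (noise_unit_sd < 0 || shift_halfwidth < 0) {
    stop("noise and shift scales must be >= 0", call. = FALSE)
  }
  structure(list(noise_small_divisor = noise_small_divisor,
                 noise_unit_sd = noise_unit_sd,
                 shift_halfwidth = shift_halfwidth,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Add i.i.d. Gaussian noise to a spectrum's intensities
#'
#' @param spectrum A [raman_spectrum()].
#' @param sd Noise standard deviation (intensity units, >= 0).
#' @return A new spectrum; wavenumbers unchanged.
#' @export
add_gaussian_noise <- function(spectrum, sd) {
  assert_spectrum(spectrum)
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (sd == 0) return(spectrum)
  raman_spectrum(spectrum$wavenumber,
                 spectrum$intensity + stats::rnorm(nrow(spectrum), 0, sd))
}

#' Shift a spectrum along the wavenumber axis
#'
#' Shifts the signal by `delta` cm^-1 and resamples it on the original grid by
#' linear interpolation: the output intensity at wavenumber w is the input
#' interpolated at `w - delta`. Positions falling outside the original support
#' are filled with the boundary intensity.
#'
#' @param spectrum A [raman_spectrum()].
#' @param delta Shift in cm^-1 (positive moves features to higher wavenumber).
#' @return A new spectrum on the same wavenumber grid.
#' @export
shift_spectrum <- function(spectrum, delta) {
  assert_spectrum(spectrum)
  if (delta == 0) return(spectrum)
  y <- stats::approx(x = spectrum$wavenumber, y = spectrum$intensity,
                     xout = spectrum$wavenumber - delta, rule = 2)$y
  raman_spectrum(spectrum$wavenumber, y)
}

variant_seed <- function(seed, spectrum_index, variant) {
  # independent stream per (spectrum, variant); kept within 32-bit range
  as.integer((as.double(seed) * 48271 + spectrum_index * 6 + variant) %%
               2147483647)
}

augment_one <- function(spectrum, variant, config, stream_seed) {
  small_sd <- max(spectrum$intensity) / config$noise_small_divisor
  withr::with_seed(stream_seed, {
    shift <- function(sp) {
      if (config$shift_halfwidth == 0) return(sp)
      shift_spectrum(sp, stats::runif(1, -config$shift_halfwidth,
                                      config$shift_halfwidth))
    }
    switch(variant,
      original    = spectrum,
      noise_small = add_gaussian_noise(spectrum, small_sd),
      noise_unit  = add_gaussian_noise(spectrum, config$noise_unit_sd),
      shift       = shift(spectrum),
      noise_small_shift = shift(add_gaussian_noise(spectrum, small_sd)),
      noise_unit_shift  = shift(add_gaussian_noise(spectrum, config$noise_unit_sd)))
  })
}

augment_variants <- c("original", "noise_small", "noise_unit", "shift",
                      "noise_small_shift", "noise_unit_shift")

#' Six-fold augmentation of a cohort
#'
#' Applies the five-transform recipe of [augment_config()] to every spectrum:
#' the output holds each original plus its five variants (a `variant` column
#' records which), with labels and patient ids inherited, so the augmented
#' cohort is exactly six times the input size. Fully reproducible from the
#' config seed, independently of processing order.
#'
#' @param cohort A [raman_cohort()].
#' @param config An [augment_config()].
#' @return A `raman_cohort` with `6 * nrow(cohort)` spectra and an added
#'   `variant` column.
#' @export
augment_sixfold <- function(cohort, config = augment_config()) {
  stopifnot(is_raman_cohort(cohort))
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    spectra <- purrr::imap(augment_variants, function(v, vi) {
      augment_one(cohort$spectrum[[i]], v, config,
                  variant_seed(config$seed, i, vi))
    })
    tibble::tibble(
      spectrum_id = paste0(cohort$spectrum_id[[i]], "_", augment_variants),
      patient_id = cohort$patient_id[[i]],
      label = cohort$label[[i]],
      variant = augment_variants,
      spectrum = spectra)
  })
  out <- dplyr::bind_rows(rows)
  restore_cohort(out)
}
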