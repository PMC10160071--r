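#' Default class profiles for synthetic chondrogenic-tumour spectra
#'
#' Each profile is a list with a peak table (`center` cm^-1, `amplitude` a.u.,
#' `width` cm^-1 half-width of a Lorentzian line), low-order polynomial
#' `baseline` coefficients (intercept, slope per 1000 cm^-1), and an additive
#' `noise_sd`. The four profiles share the common protein/collagen bands of
#' cartilage tissue (856, 938, 1003, 1245, 1450, 1660 cm^-1) and differ in a
#' few amplitudes that track malignancy grade: the DNA band at 785 cm^-1 and
#' the sulfated-glycosaminoglycan band at 1063 cm^-1 grow with grade while the
#' collagen C-C band at 938 cm^-1 shrinks. The classes are therefore visually
#' similar overall but biochemically separable, which is the premise of the
#' grading task.
#'
#' @return Named list of profiles for labels `"0"`..`"3"`.
#' @export
default_class_profiles <- function() {
  # bands common to cartilage tissue; several are close doublets
  # (856/875 proline-hydroxyproline, 1245/1270 amide III, 1440/1465 CH2),
  # which is also what makes the planar embedding of a spectrum carry loops
  base_peaks <- tibble::tibble(
    center    = c(856, 872, 1003, 1245, 1262, 1302, 1440, 1458, 1660),
    amplitude = c(28,  24,  30,   26,   22,   10,   28,   24,   30),
    width     = c(3,   3,   3.5,  3,    3,    6,    3,    3,    7))
  grade_peaks <- function(dna, gag, collagen) {
    dplyr::bind_rows(
      base_peaks,
      tibble::tibble(center = c(785, 938, 1063, 1081),
                     amplitude = c(dna, collagen, gag, 0.8 * gag),
                     width = c(3.5, 3.5, 3, 3)))
  }
  profile <- function(peaks) {
    list(peaks = peaks, baseline = c(1.0, 0.4), noise_sd = 0.3)
  }
  list(
    `0` = profile(grade_peaks(dna = 4,  gag = 8,  collagen = 26)),
    `1` = profile(grade_peaks(dna = 9,  gag = 15, collagen = 20)),
    `2` = profile(grade_peaks(dna = 15, gag = 23, collagen = 12)),
    `3` = profile(grade_peaks(dna = 20, gag = 30, collagen = 6)))
}

lorentzian <- function(x, center, width) 1 / (1 + ((x - center) / width)^2)
gaussian_line <- function(x, center, width) exp(-((x - center)^2) / (2 * width^2))

#' Evaluate a class profile without noise or patient effects
#'
#' Sum of spectral lines plus polynomial baseline; the closed form that
#' [generate_cohort()] perturbs.
#'
#' @param profile One element of [default_class_profiles()].
#' @param grid Wavenumber grid (cm^-1).
#' @param lineshape `"lorentzian"` (typical for Raman lines) or `"gaussian"`.
#' @param amp_scale Optional per-peak multiplicative factors (patient effect).
#' @return Numeric intensity vector on `grid`.
#' @export
profile_intensity <- function(profile, grid, lineshape = c("lorentzian", "gaussian"),
                              amp_scale = NULL) {
  lineshape <- match.arg(lineshape)
  shape <- if (lineshape == "lorentzian") lorentzian else gaussian_line
  peaks <- profile$peaks
  amps <- peaks$amplitude
  if (!is.null(amp_scale)) amps <- amps * amp_scale
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(peaks))) {
    y <- y + amps[[i]] * shape(grid, peaks$center[[i]], peaks$width[[i]])
  }
  b <- profile$baseline
  y + b[[1]] + b[[2]] * (grid - min(grid)) / 1000
}

#' Generate a synthetic cohort of class-structured Raman-like spectra
#'
#' Each patient draws one set of patient effects (per-peak multiplicative
#' amplitude jitter, a global intensity scale, and a small peak-position
#' shift), held fixed across that patient's spectra; each spectrum then adds
#' i.i.d. Gaussian noise. This encodes low within-patient variability relative
#' to between-patient variability, the property that makes patient-aware
#' validation behave differently from spectrum-level cross-validation.
#' Generation is a pure function of its arguments: the same seed gives a
#' bit-identical cohort.
#'
#' @param per_patient_counts Positive integer vector, spectra per patient.
#' @param patient_labels Integer labels in `{0,1,2,3}`, one per patient.
#' @param profiles Named list mapping label (as character) to a class profile;
#'   every label used must have a profile.
#' @param grid Strictly increasing wavenumber grid (cm^-1).
#' @param patient_effect_sd SD of the per-peak log-normal amplitude jitter.
#' @param patient_scale_sd SD of the per-patient global log-normal scale.
#' @param patient_shift_sd SD (cm^-1) of the per-patient peak-position shift.
#' @param noise_sd Per-spectrum additive noise SD; `NULL` uses each profile's
#'   own `noise_sd`.
#' @param lineshape Passed to [profile_intensity()].
#' @param seed Integer seed.
#' @param patient_prefix Prefix for generated patient ids.
#' @return A [raman_cohort()].
#' @export
generate_cohort <- function(per_patient_counts, patient_labels,
                            profiles = default_class_profiles(),
                            grid = seq(400, 1800, by = 4),
                            patient_effect_sd = 0.10,
                            patient_scale_sd = 0.05,
                            patient_shift_sd = 1.0,
                            noise_sd = NULL,
                            lineshape = c("lorentzian", "gaussian"),
                            seed = 1L,
                            patient_prefix = "P") {
  lineshape <- match.arg(lineshape)
  n_pat <- length(per_patient_counts)
  if (length(patient_labels) != n_pat) {
    stop("`per_patient_counts` and `patient_labels` must have equal length",
         call. = FALSE)
  }
  if (any(per_patient_counts < 1)) {
    stop("`per_patient_counts` must be positive", call. = FALSE)
  }
  check_labels(patient_labels)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing", call. = FALSE)
  missing_profiles <- setdiff(as.character(patient_labels), names(profiles))
  if (length(missing_profiles)) {
    stop("no class profile for label(s): ",
         paste(missing_profiles, collapse = ", "), call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    spectra <- list()
    patient_id <- character(0)
    label <- integer(0)
    for (p in seq_len(n_pat)) {
      lab <- as.integer(patient_labels[[p]])
      prof <- profiles[[as.character(lab)]]
      n_peaks <- nrow(prof$peaks)
      # patient effect: drawn once per patient
      amp_scale <- exp(stats::rnorm(n_peaks, 0, patient_effect_sd)) *
        exp(stats::rnorm(1, 0, patient_scale_sd))
      shift <- stats::rnorm(1, 0, patient_shift_sd)
      prof_p <- prof
      prof_p$peaks$center <- prof$peaks$center + shift
      clean <- profile_intensity(prof_p, grid, lineshape, amp_scale = amp_scale)
      sd_i <- if (is.null(noise_sd)) prof$noise_sd else noise_sd
      for (s in seq_len(per_patient_counts[[p]])) {
        noisy <- clean + stats::rnorm(length(grid), 0, sd_i)
        spectra[[length(spectra) + 1L]] <- raman_spectrum(grid, noisy)
        patient_id <- c(patient_id, sprintf("%s%02d", patient_prefix, p))
        label <- c(label, lab)
      }
    }
    raman_cohort(spectra, patient_id = patient_id, label = label)
  })
}

#' Synthetic training cohort with the reference composition
#'
#' 400 spectra from ten patients with per-patient spectrum counts
#' `c(32, 31, 37, 24, 38, 38, 50, 50, 49, 51)` and patient labels
#' `c(0, 0, 0, 1, 1, 1, 2, 2, 3, 3)`, on a 400-1800 cm^-1 grid. This is the
#' cohort composition every split-bookkeeping and validation experiment in
#' the package assumes (note classes 2 and 3 have only two patients each, so
#' leave-one-patient-out leaves a single training patient for that class).
#'
#' @param seed Integer seed.
#' @param ... Passed to [generate_cohort()] (e.g. `patient_effect_sd`).
#' @return A [raman_cohort()] of 400 spectra.
#' @export
synthetic_dataset1 <- function(seed = 1L, ...) {
  generate_cohort(per_patient_counts = c(32, 31, 37, 24, 38, 38, 50, 50, 49, 51),
                  patient_labels = c(0, 0, 0, 1, 1, 1, 2, 2, 3, 3),
                  seed = seed, patient_prefix = "P", ...)
}

#' Synthetic held-out cohort: ten new patients, one spectrum each
#'
#' Ten patients disjoint from [synthetic_dataset1()] (ids `Q01`..`Q10`), one
#' spectrum per patient, with true labels
#' `c(1, 2, 2, 1, 1, 2, 0, 3, 3, 0)` — the final-test scenario of scoring a
#' trained model on never-seen subjects.
#'
#' @inheritParams synthetic_dataset1
#' @return A [raman_cohort()] of 10 spectra.
#' @export
synthetic_dataset2 <- function(seed = 1L, ...) {
  generate_cohort(per_patient_counts = rep(1, 10),
                  patient_labels = c(1, 2, 2, 1, 1, 2, 0, 3, 3, 0),
                  seed = bitwXor(as.integer(seed), 104729L),  # distinct stream from dataset 1
                  patient_prefix = "Q", ...)
}

#' Write / read class profiles as a YAML configuration
#'
#' Serializes a named list of class profiles (peak tables, baseline
#' coefficients, noise SD) to a key-value config file readable by
#' [read_profiles()].
#'
#' @param profiles As returned by [default_class_profiles()].
#' @param path Output (input) YAML file path.
#' @return `write_profiles()`: the path, invisibly; `read_profiles()`: the
#'   profile list.
#' @export
write_profiles <- function(profiles, path) {
  ser <- lapply(profiles, function(p) {
    list(peaks = as.list(as.data.frame(p$peaks)),
         baseline = p$baseline, noise_sd = p$noise_sd)
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) {
    list(peaks = tibble::as_tibble(p$peaks),
         baseline = as.numeric(p$baseline), noise_sd = p$noise_sd)
  })
}
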