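#' Construct a single Raman spectrum
#'
#' A spectrum is a two-column tibble (`wavenumber`, `intensity`) with class
#' `raman_spectrum`. Wavenumbers are in cm^-1 and must be strictly increasing;
#' intensities are in arbitrary units and must be finite. Rows supplied out of
#' order are sorted; duplicate wavenumbers are rejected.
#'
#' @param wavenumber Numeric vector of Raman shifts (cm^-1), length >= 2.
#' @param intensity Numeric vector of scattered intensities (a.u.), same length.
#' @return A `raman_spectrum` tibble with columns `wavenumber`, `intensity`.
#' @examples
#' s <- raman_spectrum(c(400, 401, 402), c(1, 5, 2))
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  if (!is.numeric(wavenumber) || !is.numeric(intensity)) {
    stop("`wavenumber` and `intensity` must be numeric", call. = FALSE)
  }
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(wavenumber) < 2) {
    stop("a spectrum needs at least 2 points, got ", length(wavenumber), call. = FALSE)
  }
  if (anyNA(wavenumber) || any(!is.finite(wavenumber))) {
    stop("wavenumbers must be finite", call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  intensity <- intensity[ord]
  if (any(diff(wavenumber) == 0)) {
    stop("duplicate wavenumbers are not allowed", call. = FALSE)
  }
  out <- tibble::tibble(wavenumber = as.double(wavenumber),
                        intensity = as.double(intensity))
  class(out) <- c("raman_spectrum", class(out))
  out
}

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

assert_spectrum <- function(x) {
  if (is_raman_spectrum(x)) return(invisible(x))
  if (is.data.frame(x) && all(c("wavenumber", "intensity") %in% names(x))) {
    return(invisible(x))
  }
  stop("expected a raman_spectrum (tibble with `wavenumber`, `intensity`)",
       call. = FALSE)
}

#' Construct a cohort of spectra
#'
#' A cohort is a tibble with one row per spectrum and columns `spectrum_id`,
#' `patient_id`, `label` (integer in 0..3, or NA) and `spectrum` (list-column
#' of [raman_spectrum()] tibbles). All spectra of one patient must share one
#' label; `patient_order` (the order in which patients first appear) drives
#' leave-one-patient-out splitting.
#'
#' @param spectra List of `raman_spectrum` objects.
#' @param patient_id Character/factor vector, one entry per spectrum.
#' @param label Integer labels in `{0,1,2,3}` (EC = 0, CS G1 = 1, CS G2 = 2,
#'   CS G3 = 3) or `NA`.
#' @param spectrum_id Optional unique ids; generated when missing.
#' @return A `raman_cohort` tibble.
#' @export
raman_cohort <- function(spectra, patient_id, label = NA_integer_,
                         spectrum_id = NULL) {
  if (!is.list(spectra) || length(spectra) == 0) {
    stop("`spectra` must be a nonempty list of spectra", call. = FALSE)
  }
  purrr::walk(spectra, assert_spectrum)
  n <- length(spectra)
  patient_id <- as.character(rep_len(patient_id, n))
  label <- as.integer(rep_len(label, n))
  check_labels(label[!is.na(label)])
  if (is.null(spectrum_id)) {
    spectrum_id <- sprintf("s%04d", seq_len(n))
  }
  if (anyDuplicated(spectrum_id)) {
    stop("`spectrum_id` must be unique", call. = FALSE)
  }
  out <- tibble::tibble(spectrum_id = as.character(spectrum_id),
                        patient_id = patient_id,
                        label = label,
                        spectrum = spectra)
  per_patient <- tapply(out$label, out$patient_id, function(l) length(unique(l)))
  if (any(per_patient > 1)) {
    bad <- names(per_patient)[per_patient > 1][1]
    stop("patient ", bad, " has conflicting labels", call. = FALSE)
  }
  class(out) <- c("raman_cohort", class(out))
  out
}

is_raman_cohort <- function(x) inherits(x, "raman_cohort")

restore_cohort <- function(x) {
  if (!is_raman_cohort(x)) class(x) <- c("raman_cohort", class(x))
  x
}

check_labels <- function(labels) {
  if (length(labels) && !all(labels %in% 0:3)) {
    stop("labels must lie in {0, 1, 2, 3}", call. = FALSE)
  }
  invisible(labels)
}

#' Patient order of a cohort
#'
#' Patients in order of first appearance; this ordering defines the run order
#' of leave-one-patient-out validation.
#'
#' @param cohort A `raman_cohort`.
#' @return Character vector of distinct patient ids.
#' @export
patient_order <- function(cohort) {
  stopifnot(is_raman_cohort(cohort))
  unique(cohort$patient_id)
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat(sprintf("<raman_cohort> %d spectra, %d patients, labels: %s\n",
              nrow(x), length(unique(x$patient_id)),
              paste(sort(unique(x$label)), collapse = " ")))
  NextMethod()
}

# ---- file input/output -------------------------------------------------------

detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  "whitespace"
}

split_fields <- function(line, delim) {
  if (identical(delim, "whitespace")) {
    strsplit(trimws(line), "[ \t]+")[[1]]
  } else {
    trimws(strsplit(line, delim, fixed = TRUE)[[1]])
  }
}

#' Read one spectrum from a delimited text file
#'
#' Expects two numeric columns (wavenumber in cm^-1, intensity in a.u.),
#' separated by comma, tab or whitespace (auto-detected unless `delim` is
#' given). A single non-numeric leading line is treated as a header; any other
#' non-numeric row is a parse error naming its line. Rows are sorted by
#' wavenumber on read.
#'
#' @param path Path to the file.
#' @param delim `NULL` (auto), `","`, `"\t"` or `"whitespace"`.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty spectrum file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(lines[[1]])
  start <- 1L
  first <- suppressWarnings(as.numeric(split_fields(lines[[1]], delim)))
  if (anyNA(first)) start <- 2L  # header line
  if (length(lines) < start + 1L) {
    stop("spectrum file has fewer than 2 data points: ", path, call. = FALSE)
  }
  rows <- lapply(seq(start, length(lines)), function(i) {
    fields <- split_fields(lines[[i]], delim)
    if (length(fields) < 2) {
      stop("parse error at line ", i, " of ", path, ": expected 2 columns",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      stop("parse error at line ", i, " of ", path, ": non-numeric value",
           call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, rows)
  raman_spectrum(m[, 1], m[, 2])
}

#' Read a cohort from a manifest file
#'
#' The manifest is a CSV with header columns `patient_id,label,path`, one row
#' per spectrum; `path` is resolved relative to the manifest's directory.
#' All spectra of a patient must carry the same label.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param delim Delimiter passed to [read_spectrum()] for the spectrum files.
#' @return A [raman_cohort()].
#' @export
read_cohort <- function(manifest_path, delim = NULL) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) stop("empty manifest: no spectra listed", call. = FALSE)
  need <- c("patient_id", "label", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("spectrum file not found: ", missing[[1]], call. = FALSE)
  }
  spectra <- lapply(paths, read_spectrum, delim = delim)
  ids <- if ("spectrum_id" %in% names(man)) man$spectrum_id else NULL
  out <- raman_cohort(spectra, patient_id = man$patient_id,
                      label = as.integer(man$label), spectrum_id = ids)
  extra <- setdiff(names(man), c("spectrum_id", "patient_id", "label", "path"))
  for (col in extra) out[[col]] <- man[[col]]
  restore_cohort(out)
}

#' Write a cohort to delimited files plus a manifest
#'
#' One CSV per spectrum (`wavenumber,intensity`, full precision) and a
#' manifest CSV with columns `spectrum_id,patient_id,label,path`, readable
#' back with [read_cohort()].
#'
#' @param cohort A `raman_cohort`.
#' @param dir Output directory (created if absent).
#' @param manifest File name of the manifest inside `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest = "manifest.csv") {
  stopifnot(is_raman_cohort(cohort))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel <- paste0(cohort$spectrum_id, ".csv")
  for (i in seq_len(nrow(cohort))) {
    sp <- cohort$spectrum[[i]]
    con <- file.path(dir, rel[[i]])
    writeLines(c("wavenumber,intensity",
                 paste(format(sp$wavenumber, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       format(sp$intensity, digits = 17, trim = TRUE),
                       sep = ",")), con)
  }
  man <- data.frame(spectrum_id = cohort$spectrum_id,
                    patient_id = cohort$patient_id,
                    label = cohort$label, path = rel)
  # carry scalar annotation columns (e.g. augmentation variant) along
  extra <- setdiff(names(cohort), c(names(man), "spectrum", "diagram"))
  for (col in extra) if (is.atomic(cohort[[col]])) man[[col]] <- cohort[[col]]
  man_path <- file.path(dir, manifest)
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

# ---- range restriction -------------------------------------------------------

#' Restrict a spectrum or cohort to a wavenumber window
#'
#' Keeps exactly the points with `lo <= wavenumber <= hi` (closed interval).
#' The defaults select the fingerprint region 400-1800 cm^-1 used throughout
#' the classification pipeline.
#'
#' @param x A `raman_spectrum` or `raman_cohort`.
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return Object of the same type, restricted. A spectrum left with fewer
#'   than 2 points is an error.
#' @export
restrict_range <- function(x, lo = 400, hi = 1800) {
  UseMethod("restrict_range")
}

#' @export
restrict_range.raman_spectrum <- function(x, lo = 400, hi = 1800) {
  if (!(lo < hi)) stop("`lo` must be < `hi`", call. = FALSE)
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (sum(keep) < 2) {
    stop("restriction to [", lo, ", ", hi, "] leaves fewer than 2 points",
         call. = FALSE)
  }
  out <- x[keep, ]
  class(out) <- class(x)
  out
}

#' @export
restrict_range.raman_cohort <- function(x, lo = 400, hi = 1800) {
  x$spectrum <- lapply(x$spectrum, restrict_range, lo = lo, hi = hi)
  restore_cohort(x)
}

# ---- label remapping ---------------------------------------------------------

#' Remap 4-class tumour-grade labels to coarser tasks
#'
#' The four base classes are EC = 0, CS G1 = 1, CS G2 = 2, CS G3 = 3.
#' Schemes:
#' \describe{
#'   \item{`four`}{identity.}
#'   \item{`three`}{EC vs CS G1 vs CS G2+G3: 0->0, 1->1, \{2,3\}->2.}
#'   \item{`binary_ec_vs_cs`}{benign vs malignant: 0->0, \{1,2,3\}->1.}
#'   \item{`binary_low_vs_high`}{low vs high malignancy: \{0,1\}->0, \{2,3\}->1.}
#' }
#'
#' @param x Integer label vector with values in `{0,1,2,3}`, or a
#'   `raman_cohort` (whose `label` column is remapped).
#' @param scheme One of `"four"`, `"three"`, `"binary_ec_vs_cs"`,
#'   `"binary_low_vs_high"`.
#' @return Remapped labels (or cohort).
#' @examples
#' relabel(c(0, 1, 2, 3), "three")             # 0 1 2 2
#' relabel(c(0, 1, 2, 3), "binary_ec_vs_cs")   # 0 1 1 1
#' @export
relabel <- function(x, scheme = c("four", "three", "binary_ec_vs_cs",
                                  "binary_low_vs_high")) {
  UseMethod("relabel")
}

#' @export
relabel.default <- function(x, scheme = c("four", "three", "binary_ec_vs_cs",
                                          "binary_low_vs_high")) {
  scheme <- match.arg(scheme)
  labels <- as.integer(x)
  check_labels(labels)
  map <- switch(scheme,
    four = 0:3,
    three = c(0L, 1L, 2L, 2L),
    binary_ec_vs_cs = c(0L, 1L, 1L, 1L),
    binary_low_vs_high = c(0L, 0L, 1L, 1L))
  map[labels + 1L]
}

#' @export
relabel.raman_cohort <- function(x, scheme = c("four", "three",
                                               "binary_ec_vs_cs",
                                               "binary_low_vs_high")) {
  x$label <- relabel(x$label, scheme)
  restore_cohort(x)
}

#' Number of classes of a labelling scheme
#' @param scheme As in [relabel()].
#' @return Integer number of distinct classes the scheme can produce.
#' @export
n_classes <- function(scheme) {
  switch(match.arg(scheme, c("four", "three", "binary_ec_vs_cs",
                             "binary_low_vs_high")),
         four = 4L, three = 3L, 2L)
}
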