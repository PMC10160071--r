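#' Leave-one-patient-out splits
#'
#' One split per patient, in order of first appearance: the test set is all
#' spectra of that patient, the training set everything else. The test sets
#' partition the cohort and no patient ever straddles train and test.
#'
#' @param cohort A [raman_cohort()] with at least 2 patients.
#' @return A `split_set` tibble with columns `run`, `id` and list-columns
#'   `train`, `test` of row indices into the cohort.
#' @export
lopo_splits <- function(cohort) {
  stopifnot(is_raman_cohort(cohort))
  patients <- patient_order(cohort)
  if (length(patients) < 2) {
    stop("leave-one-patient-out needs >= 2 patients", call. = FALSE)
  }
  idx <- seq_len(nrow(cohort))
  out <- tibble::tibble(
    run = seq_along(patients),
    id = patients,
    test = lapply(patients, function(p) idx[cohort$patient_id == p]),
    train = lapply(patients, function(p) idx[cohort$patient_id != p]))
  new_split_set(out, scheme = "lopo")
}

#' Shuffled k-fold splits (ignoring patient boundaries)
#'
#' Plain k-fold cross-validation on spectra: spectra from the same patient can
#' occur in both train and test. Folds are a shuffled partition with sizes
#' differing by at most one; not stratified.
#'
#' @param cohort A [raman_cohort()].
#' @param k Number of folds (default 10); `k = nrow(cohort)` is leave-one-out.
#' @param seed Integer seed for the shuffle.
#' @return A `split_set` tibble, as in [lopo_splits()].
#' @export
kfold_splits <- function(cohort, k = 10L, seed = 1L) {
  stopifnot(is_raman_cohort(cohort))
  n <- nrow(cohort)
  if (k > n) stop("k = ", k, " exceeds the number of spectra (", n, ")",
                  call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  fold <- withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(k), length.out = n))
  })
  idx <- seq_len(n)
  out <- tibble::tibble(
    run = seq_len(k),
    id = sprintf("fold%02d", seq_len(k)),
    test = lapply(seq_len(k), function(f) idx[fold == f]),
    train = lapply(seq_len(k), function(f) idx[fold != f]))
  new_split_set(out, scheme = "kfold")
}

#' Static patient-level train/test split
#'
#' Training set = all spectra of the listed patients; test set = the rest.
#' Patients can be given as positions in [patient_order()] (the default
#' `c(1, 3, 5, 6, 8, 10)` is the comparison split used with the augmented
#' cohort) or as patient ids.
#'
#' @param cohort A [raman_cohort()].
#' @param train_patients Positions in patient order (numeric) or patient ids
#'   (character).
#' @return A single-run `split_set` tibble.
#' @export
static_split <- function(cohort, train_patients = c(1, 3, 5, 6, 8, 10)) {
  stopifnot(is_raman_cohort(cohort))
  patients <- patient_order(cohort)
  if (is.numeric(train_patients)) {
    if (any(train_patients < 1 | train_patients > length(patients))) {
      stop("unknown patient position in `train_patients`", call. = FALSE)
    }
    train_ids <- patients[train_patients]
  } else {
    unknown <- setdiff(train_patients, patients)
    if (length(unknown)) {
      stop("unknown patient id: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    train_ids <- train_patients
  }
  idx <- seq_len(nrow(cohort))
  train <- idx[cohort$patient_id %in% train_ids]
  test <- setdiff(idx, train)
  if (length(test) == 0) {
    stop("static split leaves an empty test set", call. = FALSE)
  }
  out <- tibble::tibble(run = 1L, id = "static",
                        test = list(test), train = list(train))
  new_split_set(out, scheme = "static")
}

new_split_set <- function(tbl, scheme) {
  attr(tbl, "scheme") <- scheme
  class(tbl) <- c("split_set", class(tbl))
  tbl
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set> scheme=%s, %d run(s)\n", attr(x, "scheme"), nrow(x)))
  NextMethod()
}
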