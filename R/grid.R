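#' Build a method grid of (vectorization, classifier) pairs
#'
#' The default grid crosses the standard parameter sets — persistence images
#' with `sigma` in `{0.1, 1, 10}` and resolution in `{5, 10, 25}`;
#' landscapes, silhouettes and Betti curves with resolution in
#' `{25, 50, 75, 100}` — with all four fusion strategies and the default
#' classifier grid. Rows are in canonical order (vectorization method, then
#' parameters, then fusion, then classifier); ties anywhere downstream are
#' broken by this ordering.
#'
#' @param methods Vectorization methods to include.
#' @param fusions Fusion strategies to include.
#' @param classifiers List of [classifier_spec()]s.
#' @param pi_sigma,pi_resolution PI parameter grids.
#' @param curve_resolution Resolution grid for PL/PS/BC.
#' @param landscape_count,silhouette_power Fixed PL/PS parameters.
#' @return A `method_grid` tibble with columns `method_id`, `vectorization`,
#'   `fusion`, `classifier` and list-columns `config`, `clf`.
#' @export
method_grid <- function(methods = c("PI", "PL", "PS", "BC"),
                        fusions = c("H0", "H1", "fused", "concat"),
                        classifiers = default_classifiers(),
                        pi_sigma = c(0.1, 1, 10),
                        pi_resolution = c(5, 10, 25),
                        curve_resolution = c(25, 50, 75, 100),
                        landscape_count = 5L,
                        silhouette_power = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  fusions <- match.arg(fusions, c("H0", "H1", "fused", "concat"),
                       several.ok = TRUE)
  configs <- list()
  for (m in methods) {
    params <- if (m == "PI") {
      expand.grid(sigma = pi_sigma, resolution = pi_resolution)
    } else {
      expand.grid(sigma = NA_real_, resolution = curve_resolution)
    }
    params <- params[order(params$sigma, params$resolution), , drop = FALSE]
    for (r in seq_len(nrow(params))) for (fu in fusions) {
      cfg <- if (m == "PI") {
        vec_config("PI", resolution = params$resolution[r],
                   sigma = params$sigma[r], fusion = fu)
      } else {
        vec_config(m, resolution = params$resolution[r],
                   landscape_count = landscape_count,
                   silhouette_power = silhouette_power, fusion = fu)
      }
      configs[[length(configs) + 1L]] <- cfg
    }
  }
  rows <- purrr::map(configs, function(cfg) {
    tibble::tibble(
      vectorization = cfg$method,
      fusion = cfg$fusion,
      classifier = vapply(classifiers, classifier_id, character(1)),
      config = list(cfg),
      clf = classifiers)
  })
  out <- dplyr::bind_rows(rows)
  out$method_id <- paste(vapply(out$config, vec_config_id, character(1)),
                         out$classifier, sep = " + ")
  out <- out[, c("method_id", "vectorization", "fusion", "classifier",
                 "config", "clf")]
  class(out) <- c("method_grid", class(out))
  out
}

derived_seed <- function(seed, run, j) {
  as.integer((as.double(seed) * 69621 + run * 1013 + j * 7) %% 2147483647)
}

#' Run a (vectorization, classifier) grid over validation splits
#'
#' For every split and method: fit the vectorization value range and the
#' classifier on the training indices only, predict the test indices, and
#' record the accuracy. Deterministic given `seed`. A method that fails to
#' fit on some split is recorded as `NA` with a warning rather than aborting
#' the grid.
#'
#' @param diagrams List of `persistence_diagram`s, one per spectrum (e.g. the
#'   `diagram` column of [compute_diagrams()]).
#' @param labels Integer labels aligned with `diagrams`.
#' @param splits A `split_set` from [lopo_splits()], [kfold_splits()] or
#'   [static_split()].
#' @param methods A [method_grid()].
#' @param seed Integer master seed.
#' @param audit Record which spectrum indices reach the fitting paths (for
#'   leakage checks); retrieved with `attr(result, "fit_log")`.
#' @return A `grid_result` tibble with columns `run`, `method_id`,
#'   `vectorization`, `fusion`, `classifier`, `accuracy`.
#' @export
run_grid <- function(diagrams, labels, splits, methods, seed = 1L,
                     audit = FALSE) {
  stopifnot(inherits(splits, "split_set"), inherits(methods, "method_grid"))
  if (nrow(methods) == 0) stop("`methods` is empty", call. = FALSE)
  labels <- as.integer(labels)
  if (length(diagrams) != length(labels)) {
    stop("`diagrams` and `labels` lengths differ", call. = FALSE)
  }
  fit_log <- list()
  results <- list()
  cfg_key <- vapply(methods$config, vec_config_id, character(1))
  for (r in seq_len(nrow(splits))) {
    train <- splits$train[[r]]
    test <- splits$test[[r]]
    if (audit) fit_log[[r]] <- sort(train)
    # share feature matrices between classifiers with the same vectorization
    for (key in unique(cfg_key)) {
      rows_k <- which(cfg_key == key)
      cfg <- methods$config[[rows_k[[1]]]]
      feats <- tryCatch({
        fitted <- fit_value_range(diagrams[train], cfg)
        list(train = vectorize_all(diagrams[train], fitted),
             test = vectorize_all(diagrams[test], fitted))
      }, error = function(e) e)
      for (j in rows_k) {
        acc <- NA_real_
        if (inherits(feats, "error")) {
          warning("method ", methods$method_id[[j]], " failed on run ", r,
                  ": ", conditionMessage(feats), call. = FALSE)
        } else {
          acc <- tryCatch({
            model <- fit_classifier(methods$clf[[j]], feats$train,
                                    labels[train],
                                    seed = derived_seed(seed, r, j))
            accuracy(predict_labels(model, feats$test), labels[test])
          }, error = function(e) {
            warning("method ", methods$method_id[[j]], " failed on run ", r,
                    ": ", conditionMessage(e), call. = FALSE)
            NA_real_
          })
        }
        results[[length(results) + 1L]] <- tibble::tibble(
          run = splits$run[[r]],
          method_id = methods$method_id[[j]],
          vectorization = methods$vectorization[[j]],
          fusion = methods$fusion[[j]],
          classifier = methods$classifier[[j]],
          accuracy = acc)
      }
    }
  }
  out <- dplyr::bind_rows(results)
  # restore canonical method order within each run
  out <- out[order(out$run, match(out$method_id, methods$method_id)), ]
  attr(out, "scheme") <- attr(splits, "scheme")
  attr(out, "n_runs") <- nrow(splits)
  attr(out, "seed") <- as.integer(seed)
  if (audit) attr(out, "fit_log") <- fit_log
  class(out) <- c("grid_result", class(out))
  out
}

#' Classification accuracy
#'
#' Fraction of positions where predicted and true labels agree
#' (1 minus the normalised Hamming distance).
#'
#' @param pred,truth Equal-length label vectors (length >= 1).
#' @return Fraction in \[0, 1\].
#' @examples
#' accuracy(c(0, 1, 1), c(0, 1, 0))  # 2/3
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` lengths differ", call. = FALSE)
  }
  if (length(pred) == 0) stop("empty label vectors", call. = FALSE)
  mean(pred == truth)
}

#' Confusion matrix of predicted vs true labels
#'
#' Entry (i, j) counts spectra with true label i - 1 predicted as j - 1; row
#' sums are the true class counts.
#'
#' @param pred,truth Integer labels in `[0, n_labels)`.
#' @param n_labels Number of classes.
#' @return `n_labels` x `n_labels` integer matrix with dimnames
#'   `true`/`predicted`.
#' @export
confusion_matrix <- function(pred, truth, n_labels) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` lengths differ", call. = FALSE)
  }
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (any(c(pred, truth) < 0 | c(pred, truth) >= n_labels)) {
    stop("labels must lie in [0, ", n_labels, ")", call. = FALSE)
  }
  lv <- 0:(n_labels - 1)
  m <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  m <- unclass(m)
  dimnames(m) <- list(true = lv, predicted = lv)
  m
}

#' Per-run best accuracy (and achieving method)
#'
#' For each run (and, by default, each fusion strategy — the shape of the
#' per-run result tables) returns the maximum accuracy over methods and the
#' first method achieving it in canonical order. The summary across runs uses
#' the population standard deviation.
#'
#' @param result A `grid_result`.
#' @param by_fusion Group by fusion strategy (default `TRUE`).
#' @return Tibble with columns `run`, (`fusion`,) `accuracy`, `method_id`;
#'   the across-run `mean` and `sd` per group are in
#'   `attr(., "summary")`.
#' @export
best_per_run <- function(result, by_fusion = TRUE) {
  stopifnot(inherits(result, "grid_result"))
  groups <- if (by_fusion) c("run", "fusion") else "run"
  ok <- result[!is.na(result$accuracy), ]
  if (nrow(ok) == 0) stop("no successful methods in the grid result", call. = FALSE)
  best <- ok |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::slice(which.max(accuracy)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(groups), accuracy, method_id)
  sum_groups <- setdiff(groups, "run")
  summ <- best |>
    dplyr::group_by(dplyr::across(dplyr::all_of(sum_groups))) |>
    dplyr::summarise(mean = mean(accuracy), sd = sd_pop(accuracy),
                     .groups = "drop")
  attr(best, "summary") <- summ
  best
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Best single method by mean accuracy across runs
#'
#' For each fusion strategy (the shape of the best-method tables), the method
#' whose mean accuracy across runs is highest; ties go to the first method in
#' canonical ordering. Methods with failed (NA) runs are excluded.
#'
#' @param result A `grid_result`.
#' @param by_fusion Group by fusion strategy (default `TRUE`).
#' @return Tibble with columns (`fusion`,) `method_id`, `vectorization`,
#'   `classifier`, `mean_accuracy`.
#' @export
best_single_method <- function(result, by_fusion = TRUE) {
  stopifnot(inherits(result, "grid_result"))
  groups <- if (by_fusion) "fusion" else character(0)
  means <- result |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "method_id",
                                                  "vectorization",
                                                  "classifier")))) |>
    dplyr::summarise(mean_accuracy = mean(accuracy), n_ok = sum(!is.na(accuracy)),
                     .groups = "drop") |>
    dplyr::filter(!is.na(mean_accuracy))
  if (nrow(means) == 0) stop("no method succeeded on every run", call. = FALSE)
  # canonical order is the row order of the grid result
  means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::slice(which.max(mean_accuracy)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(groups), method_id, vectorization, classifier,
                  mean_accuracy)
  }

#' Ablation: classify raw spectra without topological features
#'
#' Interpolates all spectra onto a shared wavenumber grid (if needed) and
#' feeds the raw intensity vectors to the classifier grid under the same
#' splits and reporting as the topological pipeline.
#'
#' @param cohort A [raman_cohort()].
#' @param labels Integer labels; defaults to the cohort's `label` column.
#' @param splits A `split_set`.
#' @param classifiers List of [classifier_spec()]s.
#' @param seed Integer master seed.
#' @param interpolate Allow interpolation onto a common grid; if `FALSE` and
#'   the grids differ, this is an error.
#' @return A `grid_result` (vectorization `"raw"`, fusion `"none"`).
#' @export
classify_without_tda <- function(cohort, labels = NULL, splits,
                                 classifiers = default_classifiers(),
                                 seed = 1L, interpolate = TRUE) {
  stopifnot(is_raman_cohort(cohort), inherits(splits, "split_set"))
  if (is.null(labels)) labels <- cohort$label
  labels <- as.integer(labels)
  x <- spectra_matrix(cohort, interpolate = interpolate)
  results <- list()
  for (r in seq_len(nrow(splits))) {
    train <- splits$train[[r]]
    test <- splits$test[[r]]
    for (j in seq_along(classifiers)) {
      acc <- tryCatch({
        model <- fit_classifier(classifiers[[j]], x[train, , drop = FALSE],
                                labels[train],
                                seed = derived_seed(seed, r, j))
        accuracy(predict_labels(model, x[test, , drop = FALSE]), labels[test])
      }, error = function(e) {
        warning("classifier ", classifier_id(classifiers[[j]]),
                " failed on run ", r, ": ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
      results[[length(results) + 1L]] <- tibble::tibble(
        run = splits$run[[r]],
        method_id = paste("raw +", classifier_id(classifiers[[j]])),
        vectorization = "raw", fusion = "none",
        classifier = classifier_id(classifiers[[j]]),
        accuracy = acc)
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "scheme") <- attr(splits, "scheme")
  attr(out, "n_runs") <- nrow(splits)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("grid_result", class(out))
  out
}

#' Intensity matrix of a cohort on a shared wavenumber grid
#'
#' @param cohort A [raman_cohort()].
#' @param grid Target grid; `NULL` uses the first spectrum's grid restricted
#'   to the wavenumber range common to all spectra.
#' @param interpolate Linearly interpolate spectra whose grids differ; if
#'   `FALSE`, differing grids are an error.
#' @return Numeric matrix, one row per spectrum.
#' @export
spectra_matrix <- function(cohort, grid = NULL, interpolate = TRUE) {
  stopifnot(is_raman_cohort(cohort))
  grids <- lapply(cohort$spectrum, `[[`, "wavenumber")
  same <- all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1)))
  if (same && is.null(grid)) {
    return(do.call(rbind, lapply(cohort$spectrum, `[[`, "intensity")))
  }
  if (!interpolate) {
    stop("spectra are not on a shared wavenumber grid and interpolation is ",
         "disabled", call. = FALSE)
  }
  if (is.null(grid)) {
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (lo >= hi) stop("spectra have no common wavenumber support", call. = FALSE)
    g1 <- grids[[1]]
    grid <- g1[g1 >= lo & g1 <= hi]
  }
  do.call(rbind, lapply(cohort$spectrum, function(sp) {
    stats::approx(sp$wavenumber, sp$intensity, xout = grid, rule = 2)$y
  }))
}

#' Train one (vectorization, classifier) method on a full training set
#'
#' Fits the vectorization value range and the classifier on all supplied
#' diagrams — the retraining-on-everything scenario used before scoring a
#' new cohort — and returns a bundle reusable with [predict_method()].
#'
#' @param diagrams Training `persistence_diagram` list.
#' @param labels Training labels.
#' @param method One row of a [method_grid()] (subset with `grid[i, ]`).
#' @param seed Integer seed.
#' @return A `trained_method` list: fitted config, fitted classifier and the
#'   method id.
#' @export
train_method <- function(diagrams, labels, method, seed = 1L) {
  stopifnot(inherits(method, "method_grid"), nrow(method) == 1)
  cfg <- fit_value_range(diagrams, method$config[[1]])
  model <- fit_classifier(method$clf[[1]], vectorize_all(diagrams, cfg),
                          as.integer(labels), seed = as.integer(seed))
  structure(list(config = cfg, model = model,
                 method_id = method$method_id[[1]]),
            class = "trained_method")
}

#' @rdname train_method
#' @param trained A `trained_method` bundle.
#' @export
predict_method <- function(trained, diagrams) {
  stopifnot(inherits(trained, "trained_method"))
  predict_labels(trained$model, vectorize_all(diagrams, trained$config))
}
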