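#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a grid result
#'
#' One row per (run, method) with the accuracy; plain tibble output for
#' downstream dplyr/ggplot2 work.
#'
#' @param x A `grid_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.grid_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "grid_result")
  out
}

#' One-row-per-fusion summary of a grid result
#'
#' The mean and population SD of the per-run best accuracy, plus the best
#' single method, per fusion strategy.
#'
#' @param x A `grid_result`.
#' @param ... Unused.
#' @return A tibble with one row per fusion strategy.
#' @export
glance.grid_result <- function(x, ...) {
  best_runs <- best_per_run(x)
  summ <- attr(best_runs, "summary")
  best_methods <- best_single_method(x)
  if (!"fusion" %in% names(summ)) summ$fusion <- "all"
  if (!"fusion" %in% names(best_methods)) best_methods$fusion <- "all"
  dplyr::left_join(
    dplyr::rename(summ, best_run_mean = "mean", best_run_sd = "sd"),
    dplyr::select(best_methods, "fusion", best_method = "method_id",
                  best_method_mean = "mean_accuracy"),
    by = "fusion")
}

#' Tidy a persistence diagram
#' @param x A `persistence_diagram`.
#' @param ... Unused.
#' @return A plain tibble with `birth`, `death`, `dimension`, `persistence`.
#' @export
tidy.persistence_diagram <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$persistence <- out$death - out$birth
  class(out) <- setdiff(class(out), "persistence_diagram")
  out
}
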