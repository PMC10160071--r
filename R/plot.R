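#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#' @param object A `raman_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raman_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a cohort of spectra coloured by class
#' @param object A `raman_cohort`.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raman_cohort <- function(object, alpha = 0.3, ...) {
  long <- tidyr::unnest(
    dplyr::mutate(tibble::as_tibble(object),
                  spectrum = lapply(.data$spectrum, tibble::as_tibble)),
    "spectrum")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$spectrum_id,
                                     colour = factor(.data$label))) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (a.u.)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a persistence diagram
#'
#' Birth/death scatter per homology dimension; essential classes are drawn as
#' triangles at the top of the death axis.
#'
#' @param object A `persistence_diagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.persistence_diagram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  finite <- df[is.finite(df$death), ]
  ess <- df[!is.finite(df$death), ]
  top <- if (nrow(finite)) max(finite$death) * 1.05 else 1
  ess$death <- top
  ggplot2::ggplot(finite, ggplot2::aes(.data$birth, .data$death,
                                       colour = factor(.data$dimension))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = ess, shape = 17, size = 2) +
    ggplot2::labs(x = "birth", y = "death", colour = "dim") +
    ggplot2::theme_minimal()
}

#' Heatmap of grid-search accuracies
#'
#' Accuracy per run and method, faceted by fusion strategy.
#'
#' @param object A `grid_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$run), .data$method_id,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$fusion), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "run", y = NULL, fill = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot a confusion matrix
#' @param m A matrix from [confusion_matrix()].
#' @return A ggplot.
#' @export
plot_confusion <- function(m) {
  df <- as.data.frame(as.table(m))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme_minimal()
}
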