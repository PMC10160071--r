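#' Vectorization configuration for persistence diagrams
#'
#' Bundles a vectorization method, its parameters and a homology-fusion
#' strategy. Sampling ranges are fitted on training diagrams with
#' [fit_value_range()] and frozen before transforming validation or test
#' diagrams, so no information leaks across a split.
#'
#' Methods and per-method parameters:
#' \describe{
#'   \item{`"BC"`}{Betti curve at `resolution` grid points.}
#'   \item{`"PL"`}{persistence landscape, `landscape_count` levels x
#'     `resolution` points.}
#'   \item{`"PS"`}{persistence silhouette with power `silhouette_power`.}
#'   \item{`"PI"`}{persistence image, `resolution` x `resolution` pixels with
#'     Gaussian bandwidth `sigma`.}
#' }
#' Fusion strategies: `"H0"` and `"H1"` vectorize only that dimension's
#' finite intervals; `"fused"` pools all finite intervals regardless of
#' dimension into one block; `"concat"` vectorizes H0 and H1 separately and
#' concatenates the two blocks.
#'
#' @param method `"PI"`, `"PL"`, `"PS"` or `"BC"`.
#' @param resolution Grid resolution n (PI image is n x n).
#' @param sigma PI Gaussian bandwidth (> 0).
#' @param landscape_count Number k of landscape levels (PL).
#' @param silhouette_power Weight power p (PS).
#' @param fusion `"H0"`, `"H1"`, `"fused"` or `"concat"`.
#' @return A `vec_config` object (unfitted).
#' @export
vec_config <- function(method = c("BC", "PL", "PS", "PI"),
                       resolution = 50L, sigma = 1,
                       landscape_count = 5L, silhouette_power = 1,
                       fusion = c("H0", "H1", "fused", "concat")) {
  method <- match.arg(method)
  fusion <- match.arg(fusion)
  if (resolution < 2) stop("`resolution` must be >= 2", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (landscape_count < 1) stop("`landscape_count` must be >= 1", call. = FALSE)
  if (silhouette_power <= 0) stop("`silhouette_power` must be > 0", call. = FALSE)
  structure(list(method = method, resolution = as.integer(resolution),
                 sigma = sigma, landscape_count = as.integer(landscape_count),
                 silhouette_power = silhouette_power, fusion = fusion,
                 ranges = NULL),
            class = "vec_config")
}

#' @export
print.vec_config <- function(x, ...) {
  par <- switch(x$method,
    PI = sprintf("sigma=%g, n=%d", x$sigma, x$resolution),
    PL = sprintf("k=%d, n=%d", x$landscape_count, x$resolution),
    PS = sprintf("p=%g, n=%d", x$silhouette_power, x$resolution),
    BC = sprintf("n=%d", x$resolution))
  cat(sprintf("<vec_config> %s(%s), fusion=%s, %s\n", x$method, par, x$fusion,
              if (is.null(x$ranges)) "unfitted" else "fitted"))
  invisible(x)
}

#' Short human-readable id of a vectorization config
#' @param config A `vec_config`.
#' @return Character scalar, e.g. `"PI(s=1,n=10)/H0"`.
#' @export
vec_config_id <- function(config) {
  par <- switch(config$method,
    PI = sprintf("s=%g,n=%d", config$sigma, config$resolution),
    PL = sprintf("k=%d,n=%d", config$landscape_count, config$resolution),
    PS = sprintf("p=%g,n=%d", config$silhouette_power, config$resolution),
    BC = sprintf("n=%d", config$resolution))
  sprintf("%s(%s)/%s", config$method, par, config$fusion)
}

as_intervals <- function(intervals) {
  if (is_persistence_diagram(intervals)) intervals <- finite_intervals(intervals)
  if (!is.data.frame(intervals) || !all(c("birth", "death") %in% names(intervals))) {
    stop("`intervals` must have columns `birth` and `death`", call. = FALSE)
  }
  keep <- is.finite(intervals$birth) & is.finite(intervals$death)
  tibble::tibble(birth = intervals$birth[keep], death = intervals$death[keep])
}

check_range <- function(range) {
  if (length(range) != 2 || !all(is.finite(range)) || range[1] >= range[2]) {
    stop("`range` must be two finite values with tmin < tmax", call. = FALSE)
  }
  range
}

# ---- numeric-vector kernels (no data-frame overhead on the hot path) --------

clip01 <- function(v, range) pmin(pmax(v, range[1]), range[2])

# tent (triangle) functions of all intervals sampled on grid: m x n matrix
tents_of <- function(b, d, grid) {
  up <- outer(b, grid, function(bb, t) t - bb)
  down <- outer(d, grid, function(dd, t) dd - t)
  pmax(pmin(up, down), 0)
}

bc_kernel <- function(b, d, n, range) {
  if (length(b) == 0) return(rep(0, n))
  b <- clip01(b, range); d <- clip01(d, range)
  grid <- seq(range[1], range[2], length.out = n)
  colSums(outer(b, grid, `<=`) & outer(d, grid, `>`))
}

pl_kernel <- function(b, d, n, k, range) {
  out <- matrix(0, k, n)
  if (length(b) > 0) {
    b <- clip01(b, range); d <- clip01(d, range)
    grid <- seq(range[1], range[2], length.out = n)
    tents <- tents_of(b, d, grid)
    kk <- min(k, nrow(tents))
    sorted <- apply(tents, 2,
                    function(col) sort(col, decreasing = TRUE)[seq_len(kk)])
    out[seq_len(kk), ] <- matrix(sorted, nrow = kk)
  }
  as.vector(t(out))
}

ps_kernel <- function(b, d, n, p, range) {
  if (length(b) == 0) return(rep(0, n))
  b <- clip01(b, range); d <- clip01(d, range)
  w <- (d - b)^p
  if (sum(w) == 0) return(rep(0, n))
  grid <- seq(range[1], range[2], length.out = n)
  as.vector(colSums(w * tents_of(b, d, grid)) / sum(w))
}

pi_kernel <- function(b, d, sigma, n, range_b, range_p, weight_pmax) {
  if (length(b) == 0) return(rep(0, n * n))
  pers <- clip01(d - b, range_p)
  b <- clip01(b, range_b)
  if (is.null(weight_pmax)) weight_pmax <- max(pers)
  w <- if (weight_pmax > 0) pmin(pmax(pers / weight_pmax, 0), 1) else
    rep(0, length(pers))
  hb <- diff(range_b) / n
  hp <- diff(range_p) / n
  cb <- range_b[1] + hb * (seq_len(n) - 0.5)   # pixel midpoints
  cp <- range_p[1] + hp * (seq_len(n) - 0.5)
  gb <- stats::dnorm(outer(b, cb, `-`), sd = sigma)      # m x n
  gp <- stats::dnorm(outer(pers, cp, `-`), sd = sigma)   # m x n
  as.vector(t(gb) %*% (w * gp) * hb * hp)                # birth index fastest
}

#' Betti curve of a set of finite intervals
#'
#' `values[i] = #\{(b, d) : b <= t_i < d\}` at `n` equally spaced grid points
#' `t_i` spanning `range` (endpoints included). Intervals are clipped to the
#' range first, so the curve of a union of diagrams equals the sum of the
#' individual curves at the same range and resolution.
#'
#' @param intervals Data frame with `birth`/`death` columns, or a
#'   `persistence_diagram` (its finite intervals are used).
#' @param n Resolution (number of grid points).
#' @param range Sampling range `c(tmin, tmax)`, `tmin < tmax`.
#' @return Numeric vector of length `n` (non-negative integer counts).
#' @examples
#' betti_curve(data.frame(birth = 0, death = 2), n = 5, range = c(0, 2))
#' @export
betti_curve <- function(intervals, n, range) {
  iv <- as_intervals(intervals)
  bc_kernel(iv$birth, iv$death, n, check_range(range))
}

#' Persistence landscape of a set of finite intervals
#'
#' The j-th landscape `lambda_j(t)` is the j-th largest tent value
#' `max(0, min(t - b, d - t))` over the intervals; levels beyond the number
#' of intervals are identically zero. Returns the concatenation of
#' `lambda_1 .. lambda_k`, each sampled at `n` points.
#'
#' @inheritParams betti_curve
#' @param k Number of landscape levels.
#' @return Numeric vector of length `k * n`.
#' @export
persistence_landscape <- function(intervals, n, k, range) {
  iv <- as_intervals(intervals)
  pl_kernel(iv$birth, iv$death, n, k, check_range(range))
}

#' Persistence silhouette of a set of finite intervals
#'
#' Weighted average of the tent functions with weights `(d - b)^p`:
#' `phi(t) = sum_i w_i tent_i(t) / sum_i w_i`. A diagram with no interval, or
#' only zero-persistence intervals (all weights zero), gives the zero vector.
#'
#' @inheritParams betti_curve
#' @param p Weight power (> 0).
#' @return Numeric vector of length `n`.
#' @export
persistence_silhouette <- function(intervals, n, p, range) {
  iv <- as_intervals(intervals)
  ps_kernel(iv$birth, iv$death, n, p, check_range(range))
}

#' Persistence image of a set of finite intervals
#'
#' Each interval is mapped to birth-persistence coordinates (b, d - b),
#' smoothed with a unit-mass isotropic Gaussian of bandwidth `sigma`, and
#' weighted linearly by persistence (zero weight at zero persistence, weight
#' one at `weight_pmax`). Pixel values integrate the weighted density over an
#' `n x n` grid spanning `range_b` x `range_p`, approximated by midpoint
#' evaluation times pixel area. Points outside the ranges are clipped to the
#' boundary.
#'
#' @inheritParams betti_curve
#' @param sigma Gaussian bandwidth (> 0).
#' @param range_b,range_p Birth and persistence axis ranges.
#' @param weight_pmax Persistence at which the linear weight reaches 1;
#'   defaults to the maximum persistence among `intervals` (use the fitted
#'   training maximum for train/test consistency).
#' @return Numeric vector of length `n^2` (image flattened row-major: birth
#'   axis fastest).
#' @export
persistence_image <- function(intervals, sigma, n, range_b, range_p,
                              weight_pmax = NULL) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  iv <- as_intervals(intervals)
  check_range(range_b); check_range(range_p)
  pi_kernel(iv$birth, iv$death, sigma, n, range_b, range_p, weight_pmax)
}

# ---- fitted ranges and dispatch ---------------------------------------------

fusion_blocks <- function(fusion) {
  switch(fusion, H0 = "h0", H1 = "h1", fused = "pooled", concat = c("h0", "h1"))
}

# plain list(b =, d =) extraction: the hot path avoids tibble construction
block_bd <- function(diagram, block) {
  keep <- is.finite(diagram$death)
  if (block != "pooled") {
    keep <- keep & diagram$dimension == (if (block == "h0") 0L else 1L)
  }
  list(b = diagram$birth[keep], d = diagram$death[keep])
}

#' Fit sampling ranges of a vectorization config on training diagrams
#'
#' Ranges are `[min finite birth, max finite death]` over the training
#' diagrams for the curve methods, and separate birth / persistence ranges
#' (plus the linear-weight maximum) for persistence images, computed per
#' fusion block. Fitting must use training diagrams only; the returned config
#' is frozen and clips out-of-range test intervals to the boundary. A block
#' with no intervals in any training diagram gets a degenerate unit range and
#' always vectorizes to zeros; if no relevant block has any interval, this is
#' an error.
#'
#' @param diagrams List of `persistence_diagram`s (training set only).
#' @param config A [vec_config()].
#' @return The fitted `vec_config`.
#' @export
fit_value_range <- function(diagrams, config) {
  stopifnot(inherits(config, "vec_config"))
  if (is_persistence_diagram(diagrams)) diagrams <- list(diagrams)
  if (length(diagrams) == 0) stop("no training diagrams supplied", call. = FALSE)
  blocks <- fusion_blocks(config$fusion)
  ranges <- list()
  any_intervals <- FALSE
  for (blk in blocks) {
    bd <- lapply(diagrams, block_bd, block = blk)
    iv <- list(birth = unlist(lapply(bd, `[[`, "b"), use.names = FALSE),
               death = unlist(lapply(bd, `[[`, "d"), use.names = FALSE))
    if (length(iv$birth) == 0) {
      ranges[[blk]] <- list(empty = TRUE, range = c(0, 1),
                            range_b = c(0, 1), range_p = c(0, 1),
                            weight_pmax = 1)
      next
    }
    any_intervals <- TRUE
    pad <- function(r) if (r[1] == r[2]) r + c(-0.5, 0.5) else r
    pers <- iv$death - iv$birth
    ranges[[blk]] <- list(
      empty = FALSE,
      range = pad(c(min(iv$birth), max(iv$death))),
      range_b = pad(range(iv$birth)),
      range_p = pad(c(min(pers), max(pers))),
      weight_pmax = max(pers))
  }
  if (!any_intervals) {
    stop("cannot fit value range: no finite intervals in any training diagram",
         call. = FALSE)
  }
  config$ranges <- ranges
  config
}

vectorize_block <- function(bd, config, rg) {
  if (isTRUE(rg$empty)) return(rep(0, block_length(config)))
  switch(config$method,
    BC = bc_kernel(bd$b, bd$d, config$resolution, rg$range),
    PL = pl_kernel(bd$b, bd$d, config$resolution, config$landscape_count,
                   rg$range),
    PS = ps_kernel(bd$b, bd$d, config$resolution, config$silhouette_power,
                   rg$range),
    PI = pi_kernel(bd$b, bd$d, config$sigma, config$resolution,
                   rg$range_b, rg$range_p, weight_pmax = rg$weight_pmax))
}

block_length <- function(config) {
  switch(config$method,
    BC = config$resolution,
    PS = config$resolution,
    PL = config$resolution * config$landscape_count,
    PI = config$resolution^2)
}

#' Length of the feature vector a config produces
#' @param config A `vec_config`.
#' @return Integer vector length (`concat` doubles the block length).
#' @export
feature_length <- function(config) {
  block_length(config) * if (config$fusion == "concat") 2L else 1L
}

#' Vectorize one persistence diagram under a fitted config
#'
#' Applies the configured method to the finite intervals selected by the
#' fusion strategy. `fit_value_range()` must have been called first.
#'
#' @param diagram A `persistence_diagram`.
#' @param config A fitted [vec_config()].
#' @return Numeric feature vector of length [feature_length()].
#' @export
vectorize <- function(diagram, config) {
  stopifnot(inherits(config, "vec_config"))
  if (is.null(config$ranges)) {
    stop("config has no fitted value range; call fit_value_range() on the ",
         "training diagrams first", call. = FALSE)
  }
  blocks <- fusion_blocks(config$fusion)
  out <- lapply(blocks, function(blk) {
    vectorize_block(block_bd(diagram, blk), config, config$ranges[[blk]])
  })
  unlist(out, use.names = FALSE)
}

#' Vectorize a list of diagrams into a feature matrix
#' @param diagrams List of `persistence_diagram`s.
#' @param config A fitted [vec_config()].
#' @return Numeric matrix, one row per diagram.
#' @export
vectorize_all <- function(diagrams, config) {
  if (is_persistence_diagram(diagrams)) diagrams <- list(diagrams)
  mat <- t(vapply(diagrams, vectorize, numeric(feature_length(config)),
                  config = config))
  matrix(mat, nrow = length(diagrams))
}

#' Write a feature matrix as CSV with a JSON sidecar for its config
#'
#' The sidecar (`<path>.json`) records the full vectorization configuration
#' including the fitted ranges, so the feature matrix is reproducible.
#'
#' @param features Numeric matrix from [vectorize_all()].
#' @param config The fitted [vec_config()] that produced it.
#' @param path CSV output path.
#' @return The CSV path, invisibly.
#' @export
write_features <- function(features, config, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  sidecar <- unclass(config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
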