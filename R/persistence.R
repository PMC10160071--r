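#' Embed a spectrum as a planar point cloud
#'
#' Each spectral sample becomes one point of R^2. In mode
#' `"wavenumber_intensity"` the coordinates are (wavenumber, intensity); in
#' mode `"index_intensity"` the x coordinate is the 0-based sample index.
#' With `normalize = TRUE` each coordinate is min-max scaled to \[0, 1\]
#' before any distance is computed (a constant coordinate maps to 0).
#'
#' @param spectrum A [raman_spectrum()].
#' @param mode `"wavenumber_intensity"` (default) or `"index_intensity"`.
#' @param normalize Min-max scale each axis to \[0, 1\]? Default `FALSE`
#'   (raw coordinates).
#' @return A `point_cloud` tibble with columns `x`, `y`.
#' @export
embed_spectrum <- function(spectrum,
                           mode = c("wavenumber_intensity", "index_intensity"),
                           normalize = FALSE) {
  assert_spectrum(spectrum)
  mode <- match.arg(mode)
  x <- if (mode == "wavenumber_intensity") spectrum$wavenumber
       else as.double(seq_along(spectrum$wavenumber) - 1L)
  y <- spectrum$intensity
  if (normalize) {
    x <- minmax01(x)
    y <- minmax01(y)
  }
  point_cloud(x, y)
}

minmax01 <- function(v) {
  r <- range(v)
  if (r[2] == r[1]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Construct a planar point cloud
#' @param x,y Finite coordinate vectors of equal length (>= 1 point).
#' @return A `point_cloud` tibble.
#' @export
point_cloud <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("a point cloud needs >= 1 point with matching x/y", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("point-cloud coordinates must be finite", call. = FALSE)
  }
  out <- tibble::tibble(x = as.double(x), y = as.double(y))
  class(out) <- c("point_cloud", class(out))
  out
}

new_diagram <- function(birth, death, dimension, n_points) {
  out <- tibble::tibble(birth = as.double(birth),
                        death = as.double(death),
                        dimension = as.integer(dimension))
  out <- out[order(out$dimension, out$birth, out$death), ]
  attr(out, "n_points") <- as.integer(n_points)
  class(out) <- c("persistence_diagram", class(out))
  out
}

is_persistence_diagram <- function(x) inherits(x, "persistence_diagram")

#' Finite intervals of a diagram, optionally for one homology dimension
#' @param diagram A `persistence_diagram`.
#' @param dimension `NULL` for all dimensions, or 0 / 1.
#' @return Tibble with columns `birth`, `death` (finite rows only).
#' @export
finite_intervals <- function(diagram, dimension = NULL) {
  stopifnot(is_persistence_diagram(diagram))
  keep <- is.finite(diagram$death)
  if (!is.null(dimension)) keep <- keep & diagram$dimension == dimension
  tibble::tibble(birth = diagram$birth[keep], death = diagram$death[keep])
}

#' Vietoris-Rips persistence diagram (H0 and H1) of a planar point cloud
#'
#' Grows balls of common radius around every point; a simplex enters the
#' filtration when all its pairwise distances are below twice the radius
#' (i.e. at its diameter). H0 intervals all have birth 0; their finite deaths
#' are exactly the edge lengths of a Euclidean minimum spanning tree, and one
#' essential interval (0, Inf) records the surviving component. H1 intervals
#' are (birth, death) pairs of loop creation and filling. The filtration is
#' truncated at the enclosing radius `min_i max_j d(i, j)`, beyond which the
#' complex is a cone (contractible), so the truncation is exact for H0/H1.
#'
#' Zero-persistence H0 intervals (coincident points, (0, 0)) are retained;
#' zero-persistence H1 edge/triangle pairs, which correspond to no homology
#' class at any filtration value, are dropped.
#'
#' @param cloud A [point_cloud()] (or a [raman_spectrum()], which is embedded
#'   with [embed_spectrum()] defaults first).
#' @param threshold Optional filtration cutoff; `NULL` uses the enclosing
#'   radius (exact). A smaller value truncates the filtration: classes still
#'   alive at the cutoff are reported as essential.
#' @return A `persistence_diagram` tibble with columns `birth`, `death`
#'   (`Inf` for essential classes) and `dimension`.
#' @examples
#' sq <- point_cloud(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' vietoris_rips_diagram(sq)  # H1 loop born at 1, filled at sqrt(2)
#' @export
vietoris_rips_diagram <- function(cloud, threshold = NULL) {
  if (is_raman_spectrum(cloud)) cloud <- embed_spectrum(cloud)
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud$x, cloud$y)
  pts <- cbind(cloud$x, cloud$y)
  res <- vr_persistence_cpp(pts, if (is.null(threshold)) -1 else threshold)
  h0 <- tibble::tibble(birth = rep(0, length(res$h0_death)),
                       death = as.double(res$h0_death), dimension = 0L)
  h0e <- tibble::tibble(birth = 0, death = Inf, dimension = 0L)
  h1 <- tibble::tibble(birth = res$h1[, 1], death = res$h1[, 2],
                       dimension = 1L)
  h1e <- tibble::tibble(birth = as.double(res$h1_essential), death = Inf,
                        dimension = 1L)
  all <- dplyr::bind_rows(h0, h0e, h1, h1e)
  new_diagram(all$birth, all$death, all$dimension, n_points = nrow(pts))
}

#' Brute-force persistence diagram by full boundary-matrix reduction
#'
#' Independent test oracle: enumerates every vertex, edge and triangle of the
#' full Vietoris-Rips complex (no threshold), orders them by (filtration
#' value, dimension, lexicographic index) and reduces the complete boundary
#' matrix over GF(2) with the standard left-to-right column algorithm. Shares
#' no code with [vietoris_rips_diagram()] (no union-find, no minimum spanning
#' tree, no truncation). Limited to small clouds.
#'
#' @param cloud A [point_cloud()] with at most `max_points` points.
#' @param max_points Size cap (default 12).
#' @return A `persistence_diagram`, same conventions as
#'   [vietoris_rips_diagram()] (zero-persistence H1 pairs dropped).
#' @export
brute_force_diagram <- function(cloud, max_points = 12L) {
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud$x, cloud$y)
  n <- nrow(cloud)
  if (n > max_points) {
    stop("brute-force oracle limited to ", max_points, " points, got ", n,
         call. = FALSE)
  }
  pts <- cbind(cloud$x, cloud$y)
  d <- as.matrix(stats::dist(pts))

  # enumerate simplices: list(vertices, filtration value, dim)
  simplices <- vector("list", 0)
  for (i in seq_len(n)) simplices[[length(simplices) + 1L]] <-
    list(v = i, f = 0, dim = 0L)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      simplices[[length(simplices) + 1L]] <- list(v = c(i, j), f = d[i, j],
                                                  dim = 1L)
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      simplices[[length(simplices) + 1L]] <-
        list(v = c(i, j, k), f = max(d[i, j], d[i, k], d[j, k]), dim = 2L)
    }
  }
  f <- vapply(simplices, `[[`, numeric(1), "f")
  dm <- vapply(simplices, `[[`, integer(1), "dim")
  lex <- vapply(simplices, function(s) sum(s$v * (n + 1)^(seq_along(s$v) - 1)),
                numeric(1))
  ord <- order(f, dm, lex)
  simplices <- simplices[ord]
  f <- f[ord]; dm <- dm[ord]
  pos <- integer(0)
  key <- vapply(simplices, function(s) paste(s$v, collapse = ","), character(1))
  index_of <- stats::setNames(seq_along(simplices), key)

  # boundary columns (global indices of facets, ascending)
  boundary <- lapply(simplices, function(s) {
    if (s$dim == 0L) return(integer(0))
    facets <- utils::combn(s$v, length(s$v) - 1, simplify = FALSE)
    sort(unname(index_of[vapply(facets, paste, character(1), collapse = ",")]))
  })

  ns <- length(simplices)
  lowinv <- integer(ns)          # low index -> column owning it (0 = free)
  reduced <- vector("list", ns)
  pair_death <- integer(ns)      # birth col -> death col (0 = none)
  for (j in seq_len(ns)) {
    col <- boundary[[j]]
    while (length(col)) {
      low <- col[length(col)]
      owner <- lowinv[low]
      if (owner == 0L) {
        lowinv[low] <- j
        pair_death[low] <- j
        break
      }
      col <- sort(c(setdiff(col, reduced[[owner]]),
                    setdiff(reduced[[owner]], col)))
    }
    reduced[[j]] <- col
  }

  birth <- death <- numeric(0); dimension <- integer(0)
  is_birth <- pair_death != 0L                  # simplex indices that are births
  killed <- logical(ns)
  killed[pair_death[is_birth]] <- TRUE          # death simplices
  for (j in seq_len(ns)) {
    if (length(reduced[[j]]) == 0 && !is_birth[j] && !killed[j]) {
      # positive, never killed: essential class  (no H2 tracked: dim <= 1)
      if (dm[j] <= 1L) {
        birth <- c(birth, f[j]); death <- c(death, Inf)
        dimension <- c(dimension, dm[j])
      }
    } else if (is_birth[j]) {
      b <- f[j]; dth <- f[pair_death[j]]
      if (dm[j] == 0L || dth > b) {   # keep zero-persistence H0 only
        birth <- c(birth, b); death <- c(death, dth)
        dimension <- c(dimension, dm[j])
      }
    }
  }
  new_diagram(birth, death, dimension, n_points = n)
}

#' Persistence diagrams for every spectrum of a cohort
#'
#' Adds a `diagram` list-column to the cohort. Essential intervals are kept
#' in each diagram; the vectorization stage consumes finite intervals only.
#'
#' @param cohort A [raman_cohort()].
#' @inheritParams embed_spectrum
#' @inheritParams vietoris_rips_diagram
#' @return The cohort tibble with an added `diagram` list-column.
#' @export
compute_diagrams <- function(cohort,
                             mode = c("wavenumber_intensity", "index_intensity"),
                             normalize = FALSE, threshold = NULL) {
  stopifnot(is_raman_cohort(cohort))
  mode <- match.arg(mode)
  cohort$diagram <- lapply(cohort$spectrum, function(sp) {
    vietoris_rips_diagram(embed_spectrum(sp, mode, normalize),
                          threshold = threshold)
  })
  restore_cohort(cohort)
}

#' Write / read a persistence diagram as delimited text
#'
#' Columns `birth,death,dimension`; essential intervals have `death = inf`.
#'
#' @param diagram A `persistence_diagram`.
#' @param path Output (input) file path.
#' @return `write_diagram()`: the path, invisibly; `read_diagram()`: the
#'   diagram.
#' @export
write_diagram <- function(diagram, path) {
  stopifnot(is_persistence_diagram(diagram))
  df <- as.data.frame(diagram)
  df$death <- ifelse(is.finite(df$death),
                     format(df$death, digits = 17, trim = TRUE), "inf")
  df$birth <- format(df$birth, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  death <- suppressWarnings(as.numeric(df$death))
  death[df$death %in% c("inf", "Inf")] <- Inf
  new_diagram(as.numeric(df$birth), death, as.integer(df$dimension),
              n_points = NA_integer_)
}
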