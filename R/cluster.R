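#' Clustering accuracy under optimal one-to-one label assignment
#'
#' Builds the cluster-by-label contingency table and finds the one-to-one
#' assignment of clusters to true labels maximising the matched count
#' (exact subset dynamic programme over the labels; unmatched clusters
#' contribute zero). With cluster names permuted, the accuracy is unchanged.
#'
#' @param clusters Cluster assignment vector.
#' @param truth True label vector, same length.
#' @return Fraction in \[0, 1\].
#' @export
assignment_accuracy <- function(clusters, truth) {
  if (length(clusters) != length(truth)) {
    stop("`clusters` and `truth` lengths differ", call. = FALSE)
  }
  tab <- unclass(table(clusters, truth))
  L <- ncol(tab)
  if (L > 16) stop("too many distinct labels for exact assignment", call. = FALSE)
  dp <- rep(-Inf, 2^L)
  dp[1] <- 0
  for (ki in seq_len(nrow(tab))) {
    ndp <- dp
    for (s in 0:(2^L - 1)) {
      if (!is.finite(dp[s + 1])) next
      for (l in seq_len(L)) {
        bit <- bitwShiftL(1L, l - 1L)
        if (bitwAnd(s, bit) == 0L) {
          val <- dp[s + 1] + tab[ki, l]
          ns <- bitwOr(s, bit)
          if (val > ndp[ns + 1]) ndp[ns + 1] <- val
        }
      }
    }
    dp <- ndp
  }
  max(dp) / length(truth)
}

# ---- hand-rolled clustering algorithms --------------------------------------
# (no affinity-propagation / DBSCAN / mean-shift / mini-batch k-means
#  implementation ships with the installed stack, so these are written here)

affinity_propagation_cluster <- function(x, damping = 0.9, max_iter = 200,
                                         conv_iter = 20) {
  n <- nrow(x)
  s <- -as.matrix(stats::dist(x))^2
  diag(s) <- stats::median(s[upper.tri(s)])
  s <- s + 1e-12 * matrix(stats::rnorm(n * n), n)   # break ties
  R <- A <- matrix(0, n, n)
  labels_old <- rep(-1L, n)
  stable <- 0L
  for (it in seq_len(max_iter)) {
    AS <- A + s
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- s - max1
    Rnew[cbind(seq_len(n), which1)] <- s[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    exemplars <- which(diag(A + R) > 0)
    if (length(exemplars) == 0) exemplars <- which.max(diag(A + R))
    labels <- exemplars[max.col(s[, exemplars, drop = FALSE],
                                ties.method = "first")]
    labels[exemplars] <- exemplars
    if (identical(labels, labels_old)) stable <- stable + 1L else stable <- 0L
    labels_old <- labels
    if (stable >= conv_iter) break
  }
  match(labels_old, sort(unique(labels_old)))
}

dbscan_cluster <- function(x, eps = NULL, min_pts = 5) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  if (is.null(eps)) {
    # 1.5x the median distance to the (min_pts - 1)-th neighbour: large
    # enough that typical in-cluster points are core points
    knn <- apply(d, 1, function(r) sort(r)[min_pts])
    eps <- 1.5 * stats::median(knn)
  }
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)      # 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (core[q]) {
        for (j in nb[[q]]) {
          if (labels[j] == 0L) {
            labels[j] <- cl
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  # each noise point counts as its own singleton cluster
  noise <- labels == 0L
  if (any(noise)) labels[noise] <- cl + seq_len(sum(noise))
  labels
}

mean_shift_cluster <- function(x, bandwidth = NULL, max_iter = 100,
                               tol = 1e-4) {
  d <- as.matrix(stats::dist(x))
  if (is.null(bandwidth)) {
    bandwidth <- stats::quantile(d[upper.tri(d)], 0.3)
    if (bandwidth == 0) bandwidth <- mean(d) + 1e-12
  }
  modes <- x
  for (it in seq_len(max_iter)) {
    shifted <- t(apply(modes, 1, function(m) {
      dd <- sqrt(colSums((t(x) - m)^2))
      w <- as.numeric(dd <= bandwidth)   # flat kernel
      if (sum(w) == 0) return(m)
      colSums(x * w) / sum(w)
    }))
    move <- sqrt(rowSums((shifted - modes)^2))
    modes <- shifted
    if (max(move) < tol * bandwidth) break
  }
  # merge modes closer than half a bandwidth
  labels <- integer(nrow(x))
  centers <- NULL
  for (i in seq_len(nrow(x))) {
    if (is.null(centers)) {
      centers <- modes[i, , drop = FALSE]
      labels[i] <- 1L
      next
    }
    dd <- sqrt(rowSums((centers - matrix(modes[i, ], nrow(centers),
                                         ncol(centers), byrow = TRUE))^2))
    hit <- which(dd <= bandwidth / 2)
    if (length(hit)) {
      labels[i] <- hit[[1]]
    } else {
      centers <- rbind(centers, modes[i, ])
      labels[i] <- nrow(centers)
    }
  }
  labels
}

minibatch_kmeans_cluster <- function(x, k, batch = 100, max_iter = 100) {
  n <- nrow(x)
  batch <- min(batch, n)
  centers <- x[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  for (it in seq_len(max_iter)) {
    idx <- sample.int(n, batch)
    xb <- x[idx, , drop = FALSE]
    assign_b <- max.col(-outer(rowSums(xb^2), rep(1, k)) +
                          2 * xb %*% t(centers) -
                          outer(rep(1, batch), rowSums(centers^2)),
                        ties.method = "first")
    for (b in seq_len(batch)) {
      c_i <- assign_b[[b]]
      counts[c_i] <- counts[c_i] + 1
      eta <- 1 / counts[c_i]
      centers[c_i, ] <- (1 - eta) * centers[c_i, ] + eta * xb[b, ]
    }
  }
  scores <- -outer(rowSums(x^2), rep(1, k)) + 2 * x %*% t(centers) -
    outer(rep(1, n), rowSums(centers^2))
  max.col(scores, ties.method = "first")
}

# kernlab's internal k-means step can hit an empty cluster on near-block
# kernel matrices; jitter the features slightly and retry before giving up
spectral_cluster <- function(x, k, tries = 5) {
  for (t in seq_len(tries)) {
    res <- tryCatch(as.integer(kernlab::specc(as.matrix(x), centers = k)),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    x <- x + matrix(stats::rnorm(length(x), 0, stats::sd(x) * 1e-3), nrow(x))
  }
  stop("spectral clustering failed: ", conditionMessage(res), call. = FALSE)
}

cluster_algorithms <- c("affinity_propagation", "agglomerative", "birch",
                        "dbscan", "kmeans", "minibatch_kmeans", "mean_shift",
                        "optics", "spectral", "gaussian_mixture")

run_cluster_algorithm <- function(algorithm, x, k) {
  switch(algorithm,
    kmeans = stats::kmeans(x, centers = k, nstart = 10)$cluster,
    minibatch_kmeans = minibatch_kmeans_cluster(x, k),
    agglomerative = stats::cutree(stats::hclust(stats::dist(x),
                                                method = "ward.D2"), k = k),
    gaussian_mixture = {
      mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller
      fit <- mclust::Mclust(x, G = k, modelNames = c("EII", "VII"),
                            verbose = FALSE)
      if (is.null(fit)) stop("Gaussian mixture failed to fit")
      fit$classification
    },
    spectral = spectral_cluster(x, k),
    affinity_propagation = affinity_propagation_cluster(x),
    dbscan = dbscan_cluster(x),
    mean_shift = mean_shift_cluster(x),
    birch = ,
    optics = stop("algorithm `", algorithm, "` has no implementation in this ",
                  "package", call. = FALSE),
    stop("unknown clustering algorithm: ", algorithm, call. = FALSE))
}

#' Unsupervised clustering evaluation of feature vectors
#'
#' Clusters the feature matrix with each requested algorithm and scores the
#' result against the true labels by [assignment_accuracy()]. Algorithms that
#' take a cluster count receive `k = ` number of distinct true labels; the
#' others (affinity propagation, DBSCAN, mean shift) choose their own. An
#' algorithm returning a single cluster is flagged degenerate (its accuracy
#' is the majority-class frequency).
#'
#' @param features Numeric matrix, one row per spectrum (e.g. from
#'   [vectorize_all()]).
#' @param truth Integer true labels.
#' @param algorithms Subset of `"affinity_propagation"`, `"agglomerative"`,
#'   `"dbscan"`, `"kmeans"`, `"minibatch_kmeans"`, `"mean_shift"`,
#'   `"spectral"`, `"gaussian_mixture"` (`"birch"` and `"optics"` are
#'   recognised names but have no implementation here and raise an error).
#' @param seed Integer seed (stochastic algorithms).
#' @return Tibble with columns `algorithm`, `accuracy`, `n_clusters`,
#'   `degenerate`.
#' @export
cluster_eval <- function(features,
                         truth,
                         algorithms = c("affinity_propagation", "agglomerative",
                                        "dbscan", "kmeans", "minibatch_kmeans",
                                        "mean_shift", "spectral",
                                        "gaussian_mixture"),
                         seed = 1L) {
  x <- as.matrix(features)
  if (nrow(x) == 0) stop("`features` is empty", call. = FALSE)
  if (nrow(x) != length(truth)) {
    stop("`features` rows and `truth` length differ", call. = FALSE)
  }
  algorithms <- match.arg(algorithms, cluster_algorithms, several.ok = TRUE)
  k <- length(unique(truth))
  rows <- purrr::map(algorithms, function(alg) {
    cl <- withr::with_seed(as.integer(seed), run_cluster_algorithm(alg, x, k))
    nc <- length(unique(cl))
    degenerate <- nc == 1
    acc <- if (degenerate) {
      max(table(truth)) / length(truth)
    } else {
      assignment_accuracy(cl, truth)
    }
    tibble::tibble(algorithm = alg, accuracy = acc, n_clusters = nc,
                   degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}
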