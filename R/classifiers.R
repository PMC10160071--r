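#' Classifier specification
#'
#' The three classifier families of the grid:
#' \describe{
#'   \item{`svc_rbf`}{support vector classifier with RBF kernel, cost `C`
#'     (grid `{1, 2, 3, 5, 10, 20}`), one-vs-one for multiclass, features
#'     used unscaled with the `1 / (p * var(X))` bandwidth heuristic.}
#'   \item{`random_forest`}{random forest with `n_trees` trees (default 100).}
#'   \item{`ridge`}{ridge regression used as a classifier: labels one-hot
#'     encoded to +/-1, linear L2-penalised fit with penalty `alpha`
#'     (default 1, intercept unpenalised), prediction by argmax.}
#' }
#'
#' @param kind `"svc_rbf"`, `"random_forest"` or `"ridge"`.
#' @param C SVC cost parameter.
#' @param n_trees Number of forest trees.
#' @param alpha Ridge penalty.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("svc_rbf", "random_forest", "ridge"),
                            C = 1, n_trees = 100L, alpha = 1) {
  kind <- match.arg(kind)
  if (kind == "svc_rbf" && C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (kind == "random_forest" && n_trees < 1) {
    stop("`n_trees` must be >= 1", call. = FALSE)
  }
  if (kind == "ridge" && alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  structure(list(kind = kind, C = C, n_trees = as.integer(n_trees),
                 alpha = alpha),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", classifier_id(x), "\n")
  invisible(x)
}

#' Short id of a classifier spec
#' @param spec A `classifier_spec`.
#' @return Character scalar, e.g. `"SVC(C=5)"`.
#' @export
classifier_id <- function(spec) {
  switch(spec$kind,
    svc_rbf = sprintf("SVC(C=%g)", spec$C),
    random_forest = sprintf("RFC(trees=%d)", spec$n_trees),
    ridge = sprintf("Ridge(alpha=%g)", spec$alpha))
}

#' Default classifier grid
#'
#' SVC with `C` in `{1, 2, 3, 5, 10, 20}`, a 100-tree random forest, and the
#' ridge classifier with `alpha = 1`.
#'
#' @return List of [classifier_spec()] objects.
#' @export
default_classifiers <- function() {
  c(lapply(c(1, 2, 3, 5, 10, 20), function(C) classifier_spec("svc_rbf", C = C)),
    list(classifier_spec("random_forest"), classifier_spec("ridge")))
}

#' Fit a classifier on a feature matrix
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix (rows = samples).
#' @param y Integer class labels.
#' @param seed Integer seed (controls forest randomness).
#' @return A fitted model usable with [predict_labels()].
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) == 1) {
    return(structure(list(constant = classes), class = "ramantda_constant"))
  }
  withr::with_seed(as.integer(seed), {
    model <- switch(spec$kind,
      svc_rbf = {
        v <- stats::var(as.vector(x))
        gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
        e1071::svm(x = x, y = factor(y, levels = classes), kernel = "radial",
                   cost = spec$C, gamma = gamma, scale = FALSE)
      },
      random_forest = randomForest::randomForest(
        x = x, y = factor(y, levels = classes), ntree = spec$n_trees),
      ridge = fit_ridge(x, y, classes, spec$alpha))
    structure(list(model = model, kind = spec$kind, classes = classes),
              class = "ramantda_model")
  })
}

fit_ridge <- function(x, y, classes, alpha) {
  # one-hot +/-1 targets, centred closed-form solve; intercept unpenalised
  Y <- sapply(classes, function(cl) ifelse(y == cl, 1, -1))
  xm <- colMeans(x)
  ym <- colMeans(Y)
  xc <- sweep(x, 2, xm)
  yc <- sweep(Y, 2, ym)
  p <- ncol(x)
  W <- solve(crossprod(xc) + diag(alpha, p), crossprod(xc, yc))
  list(W = W, intercept = ym - as.vector(xm %*% W), x_mean = xm)
}

#' Predict integer labels from a fitted model
#' @param model Result of [fit_classifier()].
#' @param x Feature matrix.
#' @return Integer label vector.
#' @export
predict_labels <- function(model, x) {
  x <- as.matrix(x)
  if (inherits(model, "ramantda_constant")) {
    return(rep(model$constant, nrow(x)))
  }
  stopifnot(inherits(model, "ramantda_model"))
  switch(model$kind,
    svc_rbf = as.integer(as.character(stats::predict(model$model, x))),
    random_forest = as.integer(as.character(stats::predict(model$model, x))),
    ridge = {
      scores <- x %*% model$model$W +
        matrix(model$model$intercept, nrow(x), length(model$classes),
               byrow = TRUE)
      model$classes[max.col(scores, ties.method = "first")]
    })
}
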