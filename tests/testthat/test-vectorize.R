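iv <- function(...) {
  v <- c(...)
  if (is.null(v)) return(data.frame(birth = numeric(0), death = numeric(0)))
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(birth = m[, 1], death = m[, 2])
}

test_that("betti_curve counts covering intervals on the closed grid", {
  # two nested intervals: count 2 at t = 0.5, count 1 at t = 1.5
  bc <- betti_curve(iv(0, 1, 0, 2), n = 5, range = c(0, 2))
  expect_equal(bc, c(2, 2, 1, 1, 0))   # t = 0, .5, 1, 1.5, 2 with b <= t < d

  expect_equal(betti_curve(iv(0, 2), n = 5, range = c(0, 2)),
               c(1, 1, 1, 1, 0))
  expect_equal(betti_curve(data.frame(birth = numeric(0), death = numeric(0)),
                           n = 7, range = c(0, 1)), rep(0, 7))

  # additivity: curve of a union is the sum of the curves
  a <- iv(0, 1, 0.5, 2)
  b <- iv(0.2, 0.9)
  both <- rbind(a, b)
  r <- c(0, 2)
  expect_equal(betti_curve(both, 25, r),
               betti_curve(a, 25, r) + betti_curve(b, 25, r))

  # non-negative integers always
  set.seed(1)
  rd <- data.frame(birth = runif(20), death = runif(20) + 1)
  vals <- betti_curve(rd, 33, c(0, 2))
  expect_true(all(vals >= 0 & vals == round(vals)))

  expect_error(betti_curve(a, 10, c(1, 1)), "tmin")
})

test_that("persistence_landscape computes ordered tent levels", {
  # single interval: lambda_1 is its tent, lambda_2 vanishes
  pl <- persistence_landscape(iv(0, 2), n = 5, k = 2, range = c(0, 2))
  expect_equal(pl[1:5], c(0, 0.5, 1, 0.5, 0))
  expect_equal(pl[6:10], rep(0, 5))

  # two overlapping intervals: second level at t = 1.5 equals 0.5
  pl2 <- persistence_landscape(iv(0, 2, 1, 3), n = 7, k = 2, range = c(0, 3))
  grid <- seq(0, 3, length.out = 7)
  l2 <- pl2[8:14]
  expect_equal(l2[grid == 1.5], 0.5)

  expect_equal(persistence_landscape(iv(), n = 4, k = 3, range = c(0, 1)),
               rep(0, 12))

  # pointwise ordering of levels on random diagrams
  set.seed(2)
  for (rep in 1:20) {
    b <- runif(6)
    d <- b + runif(6)
    lv <- matrix(persistence_landscape(data.frame(birth = b, death = d),
                                       n = 40, k = 4, range = c(0, 2)),
                 nrow = 4, byrow = TRUE)
    expect_true(all(diff(lv) <= 1e-12))   # lambda_1 >= lambda_2 >= ...
  }
})

test_that("persistence_silhouette is the weighted tent average", {
  # one interval: weights cancel, silhouette is its tent
  ps <- persistence_silhouette(iv(0, 2), n = 5, p = 1, range = c(0, 2))
  expect_equal(ps, c(0, 0.5, 1, 0.5, 0))

  # weights 2/3 and 1/3 at t = 1: tents are 1 and 0
  ps2 <- persistence_silhouette(iv(0, 2, 0, 1), n = 3, p = 1, range = c(0, 2))
  expect_equal(ps2[2], 2 / 3)

  # zero-persistence-only diagram: zero vector, no division error
  expect_equal(persistence_silhouette(iv(1, 1, 2, 2), n = 4, p = 1,
                                      range = c(0, 3)), rep(0, 4))

  # large p approaches the tent of the most persistent interval
  tall <- iv(0, 2, 0.8, 1.4)
  ps8 <- persistence_silhouette(tall, n = 21, p = 8, range = c(0, 2))
  tent <- persistence_silhouette(iv(0, 2), n = 21, p = 1, range = c(0, 2))
  expect_lt(max(abs(ps8 - tent)), 0.05)
})

test_that("persistence_image integrates a weighted unit-mass Gaussian", {
  expect_equal(persistence_image(iv(), sigma = 1, n = 5, range_b = c(0, 1),
                                 range_p = c(0, 1)), rep(0, 25))

  # single interval (0, 2): argmax pixel contains (b, p) = (0, 2)
  img <- matrix(persistence_image(iv(0, 2), sigma = 0.25, n = 20,
                                  range_b = c(-1, 1), range_p = c(1, 3)),
                nrow = 20)
  idx <- which(img == max(img), arr.ind = TRUE)
  cb <- -1 + (idx[1, 1] - 0.5) * 2 / 20
  cp <- 1 + (idx[1, 2] - 0.5) * 2 / 20
  expect_lt(abs(cb - 0), 0.1)
  expect_lt(abs(cp - 2), 0.1)

  # mass: grid extending >= 4 sigma around the point sums to the weight
  s <- 0.5
  total <- sum(persistence_image(iv(0, 2), sigma = s, n = 100,
                                 range_b = c(-2.5, 2.5), range_p = c(-0.5, 4.5),
                                 weight_pmax = 2))
  expect_lt(abs(total - 1), 1e-3)
})

test_that("vectorizers are permutation invariant in the interval multiset", {
  set.seed(3)
  b <- runif(8); d <- b + runif(8)
  df <- data.frame(birth = b, death = d)
  perm <- df[sample(8), ]
  r <- c(0, 2)
  expect_equal(betti_curve(df, 30, r), betti_curve(perm, 30, r))
  expect_equal(persistence_landscape(df, 30, 3, r),
               persistence_landscape(perm, 30, 3, r))
  expect_equal(persistence_silhouette(df, 30, 2, r),
               persistence_silhouette(perm, 30, 2, r))
  expect_equal(persistence_image(df, 1, 10, r, r, weight_pmax = 1),
               persistence_image(perm, 1, 10, r, r, weight_pmax = 1))
})

test_that("fusion strategies select, pool and concatenate homology blocks", {
  d <- new_diagram(birth = c(0, 0, 0, 1, 2),
                   death = c(0.5, 1.5, Inf, 2, 3.5),
                   dimension = c(0L, 0L, 0L, 1L, 1L), n_points = 3L)
  diagrams <- list(d)

  for (m in c("BC", "PL", "PS", "PI")) {
    for (fu in c("H0", "H1", "fused", "concat")) {
      cfg <- fit_value_range(diagrams, vec_config(m, resolution = 10,
                                                  fusion = fu))
      v <- vectorize(d, cfg)
      expect_length(v, feature_length(cfg))
      expect_true(all(is.finite(v)))
    }
  }

  # concat = H0 block followed by H1 block, each with its own range
  cfg_c <- fit_value_range(diagrams, vec_config("BC", resolution = 8,
                                                fusion = "concat"))
  cfg_0 <- fit_value_range(diagrams, vec_config("BC", resolution = 8,
                                                fusion = "H0"))
  cfg_1 <- fit_value_range(diagrams, vec_config("BC", resolution = 8,
                                                fusion = "H1"))
  expect_equal(vectorize(d, cfg_c),
               c(vectorize(d, cfg_0), vectorize(d, cfg_1)))
  expect_length(vectorize(d, cfg_c), 2 * feature_length(cfg_0))

  # H1 fusion of a diagram with no loops: zero block
  d0 <- new_diagram(birth = c(0, 0), death = c(1, Inf),
                    dimension = c(0L, 0L), n_points = 2L)
  cfg_h1 <- fit_value_range(list(d), vec_config("PS", resolution = 6,
                                                fusion = "H1"))
  expect_equal(vectorize(d0, cfg_h1), rep(0, 6))

  # fused block equals H0 block when H1 is empty
  cfg_f <- fit_value_range(list(d0), vec_config("BC", resolution = 6,
                                                fusion = "fused"))
  cfg_f0 <- fit_value_range(list(d0), vec_config("BC", resolution = 6,
                                                 fusion = "H0"))
  expect_equal(vectorize(d0, cfg_f), vectorize(d0, cfg_f0))
})

test_that("value ranges are fitted on training diagrams and frozen", {
  d1 <- new_diagram(0, 1, 0L, 2L)
  d2 <- new_diagram(2, 5, 0L, 2L)
  cfg <- fit_value_range(list(d1, d2), vec_config("BC", resolution = 5,
                                                  fusion = "H0"))
  expect_equal(cfg$ranges$h0$range, c(0, 5))

  # unfitted config refuses to transform
  expect_error(vectorize(d1, vec_config("BC", fusion = "H0")), "fitted")

  # a test diagram outside the fitted range is clipped, not an error
  wide <- new_diagram(c(-3, 4), c(-1, 9), c(0L, 0L), 2L)
  v <- vectorize(wide, cfg)
  expect_true(all(is.finite(v)))

  # nothing to fit on anywhere -> error
  empty <- new_diagram(numeric(0), numeric(0), integer(0), 1L)
  expect_error(fit_value_range(list(empty), vec_config("BC", fusion = "H0")),
               "no finite intervals")
})

test_that("feature lengths follow the method formulas across the grid", {
  for (cfg in list(vec_config("PI", resolution = 10, sigma = 1),
                   vec_config("PL", resolution = 25, landscape_count = 5),
                   vec_config("PS", resolution = 75),
                   vec_config("BC", resolution = 100))) {
    expected <- switch(cfg$method, PI = 100, PL = 125, PS = 75, BC = 100)
    expect_equal(feature_length(cfg), expected)
    cfg2 <- cfg
    cfg2$fusion <- "concat"
    expect_equal(feature_length(cfg2), 2 * expected)
  }
})

test_that("feature matrices write CSV plus a JSON config sidecar", {
  d <- new_diagram(c(0, 1), c(2, 3), c(0L, 1L), 2L)
  cfg <- fit_value_range(list(d), vec_config("BC", resolution = 5,
                                             fusion = "fused"))
  X <- vectorize_all(list(d, d), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(X, cfg, path)
  back <- as.matrix(utils::read.csv(path))
  expect_equal(unname(back), unname(X))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$method, "BC")
  expect_equal(side$fusion, "fused")
  expect_equal(unlist(side$ranges$pooled$range), c(0, 3))
})
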