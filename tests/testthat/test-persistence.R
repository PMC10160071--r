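test_that("embed_spectrum maps samples to points with the requested axes", {
  s <- raman_spectrum(c(400, 401, 402), c(0, 5, 10))
  pc <- embed_spectrum(s)
  expect_equal(nrow(pc), 3)                       # cardinality preserved
  expect_equal(pc$x, c(400, 401, 402))
  expect_equal(pc$y, c(0, 5, 10))

  pci <- embed_spectrum(s, mode = "index_intensity")
  expect_equal(pci$x, c(0, 1, 2))

  pcn <- embed_spectrum(s, normalize = TRUE)
  expect_equal(pcn$y, c(0, 0.5, 1))
  expect_equal(pcn$x, c(0, 0.5, 1))
})

test_that("known small diagrams come out exactly", {
  # single point: one essential component, no loops
  d1 <- vietoris_rips_diagram(point_cloud(0, 0))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$death, Inf)
  expect_equal(d1$dimension, 0L)

  # collinear points: H0 deaths are the MST gaps {1, 2}, no H1
  d2 <- vietoris_rips_diagram(point_cloud(c(0, 1, 3), c(0, 0, 0)))
  fin <- d2[is.finite(d2$death), ]
  expect_equal(sort(fin$death[fin$dimension == 0]), c(1, 2))
  expect_equal(sum(d2$dimension == 1), 0)

  # unit square: loop born when the last side appears, filled at the diagonal
  d3 <- vietoris_rips_diagram(point_cloud(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  h1 <- d3[d3$dimension == 1 & is.finite(d3$death), ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))

  # equilateral triangle: the 2-simplex enters with its edges, no loop survives
  th <- c(0, 2 * pi / 3, 4 * pi / 3)
  d4 <- vietoris_rips_diagram(point_cloud(cos(th), sin(th)))
  expect_equal(sum(d4$dimension == 1), 0)

  # coincident points merge at filtration value 0
  d5 <- vietoris_rips_diagram(point_cloud(c(0, 0, 1), c(0, 0, 0)))
  expect_equal(sort(d5$death[d5$dimension == 0 & is.finite(d5$death)]),
               c(0, 1))
})

test_that("main implementation equals the brute-force oracle on random clouds", {
  set.seed(4211)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    pc <- point_cloud(runif(n), runif(n))
    expect_same_diagram(vietoris_rips_diagram(pc), brute_force_diagram(pc))
  }
})

test_that("oracle agreement holds on structured clouds too", {
  expect_same_diagram(vietoris_rips_diagram(ring_cloud(8)),
                      brute_force_diagram(ring_cloud(8)))
  # a ring has one prominent loop
  h1 <- vietoris_rips_diagram(ring_cloud(8))
  expect_equal(sum(h1$dimension == 1 & is.finite(h1$death)), 1)
  expect_error(brute_force_diagram(point_cloud(runif(13), runif(13))),
               "12 points")
})

test_that("H0 deaths equal Euclidean MST edge lengths (independent MST)", {
  set.seed(99)
  pc <- point_cloud(runif(40), runif(40))
  d <- vietoris_rips_diagram(pc)
  h0 <- sort(d$death[d$dimension == 0 & is.finite(d$death)])

  # Prim's algorithm on the distance matrix, written here as the cross-check
  dm <- as.matrix(dist(cbind(pc$x, pc$y)))
  n <- nrow(dm)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- dm[1, ]
  mst <- numeric(0)
  for (step in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    mst <- c(mst, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, dm[j, ])
  }
  expect_equal(h0, sort(unname(mst)), tolerance = 1e-12)

  # count bookkeeping: finite + essential H0 intervals = number of points
  expect_equal(sum(d$dimension == 0), n)
})

test_that("diagrams are translation invariant and scale equivariant", {
  set.seed(17)
  pc <- point_cloud(runif(9), runif(9))
  base <- sorted_intervals(vietoris_rips_diagram(pc))

  shifted <- point_cloud(pc$x + 13.7, pc$y - 2.2)
  expect_same_diagram(vietoris_rips_diagram(shifted), base)

  scaled <- point_cloud(3 * pc$x, 3 * pc$y)
  ds <- sorted_intervals(vietoris_rips_diagram(scaled))
  fin <- is.finite(base$death)
  expect_equal(ds$birth, 3 * base$birth, tolerance = 1e-12)
  expect_equal(ds$death[fin], 3 * base$death[fin], tolerance = 1e-12)
})

test_that("user-supplied threshold truncates the filtration and reports survivors", {
  d <- vietoris_rips_diagram(ring_cloud(12), threshold = 0.6)
  # the ring loop is born early and still alive at 0.6: reported essential
  expect_gte(sum(d$dimension == 1 & !is.finite(d$death)), 1)
})

test_that("compute_diagrams adds one diagram per spectrum", {
  co <- tiny_cohort()
  cd <- compute_diagrams(co)
  expect_true("diagram" %in% names(cd))
  expect_length(cd$diagram, nrow(co))
  np <- nrow(co$spectrum[[1]])
  expect_equal(sum(cd$diagram[[1]]$dimension == 0), np)
})

test_that("diagram serialization round-trips including essential intervals", {
  d <- vietoris_rips_diagram(ring_cloud(6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram(d, path)
  back <- read_diagram(path)
  expect_same_diagram(back, d, tol = 1e-12)
})
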