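# small in-code fixtures shared across test files

# a tiny cohort on a coarse grid: fast to embed and to run VR on
tiny_cohort <- function(seed = 1, counts = c(3, 3, 2, 2),
                        labels = c(0, 1, 2, 3), ...) {
  generate_cohort(per_patient_counts = counts, patient_labels = labels,
                  grid = seq(400, 1800, by = 25), seed = seed, ...)
}

# write a two-column spectrum file; returns the path
write_spectrum_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("spec", tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}

# a deterministic small point cloud
ring_cloud <- function(n = 8, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  point_cloud(r * cos(th), r * sin(th))
}

sorted_intervals <- function(d) {
  df <- as.data.frame(d)[, c("birth", "death", "dimension")]
  df[order(df$dimension, df$birth, df$death), ]
}

expect_same_diagram <- function(a, b, tol = 1e-9) {
  a <- sorted_intervals(a)
  b <- sorted_intervals(b)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$dimension, b$dimension)
  expect_equal(is.finite(a$death), is.finite(b$death))
  fin <- is.finite(a$death)
  expect_lt(max(abs(a$birth - b$birth), 0), tol)
  expect_lt(max(abs(a$death[fin] - b$death[fin]), 0), tol)
}
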