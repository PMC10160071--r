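test_that("read_spectrum parses, sorts and validates two-column files", {
  p <- write_spectrum_file(c("400,1.0", "401,2.0"))
  s <- read_spectrum(p)
  expect_s3_class(s, "raman_spectrum")
  expect_equal(nrow(s), 2)
  expect_equal(s$wavenumber, c(400, 401))
  expect_equal(s$intensity, c(1, 2))

  # descending input is returned sorted ascending
  p2 <- write_spectrum_file(c("900 5", "500 1", "700 3"))
  s2 <- read_spectrum(p2)
  expect_equal(s2$wavenumber, c(500, 700, 900))
  expect_equal(s2$intensity, c(1, 3, 5))

  # header line tolerated; tab dialect auto-detected
  p3 <- write_spectrum_file(c("wavenumber\tintensity", "400\t1", "404\t2"))
  expect_equal(read_spectrum(p3)$wavenumber, c(400, 404))
})

test_that("read_spectrum error contract: line numbers, size, duplicates", {
  p <- write_spectrum_file(c("400,1.0", "401,oops", "402,3"))
  expect_error(read_spectrum(p), "line 2")
  expect_error(read_spectrum(write_spectrum_file("400,1")), "fewer than 2")
  expect_error(read_spectrum(write_spectrum_file(c("400,1", "400,2"))),
               "duplicate")
  expect_error(read_spectrum(tempfile()), "not found")
})

test_that("cohort round-trips through write_cohort/read_cohort bit-identically", {
  co <- tiny_cohort(seed = 3)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  back <- read_cohort(man)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$patient_id, co$patient_id)
  expect_equal(back$label, co$label)
  for (i in seq_len(nrow(co))) {
    expect_identical(back$spectrum[[i]]$wavenumber, co$spectrum[[i]]$wavenumber)
    expect_identical(back$spectrum[[i]]$intensity, co$spectrum[[i]]$intensity)
  }
})

test_that("read_cohort enforces manifest contracts", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)

  # empty manifest
  empty <- file.path(dir, "empty.csv")
  writeLines("spectrum_id,patient_id,label,path", empty)
  expect_error(read_cohort(empty), "empty manifest")

  # conflicting labels for one patient
  m <- utils::read.csv(man)
  m$label[m$patient_id == m$patient_id[1]][1] <- 3L
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(m, bad, row.names = FALSE)
  expect_error(read_cohort(bad), "conflicting labels")

  # missing spectrum file
  m2 <- utils::read.csv(man)
  m2$path[1] <- "missing.csv"
  bad2 <- file.path(dir, "bad2.csv")
  utils::write.csv(m2, bad2, row.names = FALSE)
  expect_error(read_cohort(bad2), "not found")
})

test_that("restrict_range keeps the closed interval and is idempotent", {
  s <- raman_spectrum(seq(200, 3400, by = 100), seq_len(33))
  r <- restrict_range(s)
  expect_true(all(r$wavenumber >= 400 & r$wavenumber <= 1800))
  expect_equal(range(r$wavenumber), c(400, 1800))   # closed endpoints kept
  expect_identical(restrict_range(r), r)            # idempotent

  # already inside -> identical
  inside <- raman_spectrum(c(500, 600, 700), c(1, 2, 3))
  expect_identical(restrict_range(inside), inside)

  # integer grid, closed interval picks exactly the 2 endpoints
  g <- raman_spectrum(seq(990, 1010, by = 1), rnorm(21))
  expect_equal(restrict_range(g, 1000, 1001)$wavenumber, c(1000, 1001))

  expect_error(restrict_range(inside, 1000, 1001), "fewer than 2")
  expect_error(restrict_range(s, 500, 500), "lo")
})

test_that("relabel implements the four grading schemes", {
  expect_equal(relabel(0:3, "four"), 0:3)
  expect_equal(relabel(0:3, "three"), c(0L, 1L, 2L, 2L))
  expect_equal(relabel(0:3, "binary_ec_vs_cs"), c(0L, 1L, 1L, 1L))
  expect_equal(relabel(0:3, "binary_low_vs_high"), c(0L, 0L, 1L, 1L))

  # held-out cohort truth collapses to the printed binary labels
  truth2 <- c(1, 2, 2, 1, 1, 2, 0, 3, 3, 0)
  expect_equal(relabel(truth2, "binary_ec_vs_cs"),
               c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L, 1L, 0L))

  expect_error(relabel(c(0, 4), "four"), "labels")

  # length preserved and codomain respected for every scheme
  for (scheme in c("four", "three", "binary_ec_vs_cs", "binary_low_vs_high")) {
    out <- relabel(c(0, 1, 2, 3, 3, 0), scheme)
    expect_length(out, 6)
    expect_true(all(out < n_classes(scheme)))
  }

  co <- tiny_cohort()
  expect_equal(relabel(co, "three")$label, relabel(co$label, "three"))
})

test_that("annotation columns like the augmentation variant survive the manifest", {
  co <- tiny_cohort(seed = 4, counts = c(2, 2), labels = c(0, 1))
  aug <- augment_sixfold(co, augment_config(seed = 1))
  dir <- withr::local_tempdir()
  back <- read_cohort(write_cohort(aug, dir))
  expect_true("variant" %in% names(back))
  expect_equal(back$variant, aug$variant)
})
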