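test_that("generate_cohort respects composition and is a pure function of the seed", {
  counts <- c(32, 31, 37, 24, 38, 38, 50, 50, 49, 51)
  labels <- c(0, 0, 0, 1, 1, 1, 2, 2, 3, 3)
  co <- generate_cohort(counts, labels, grid = seq(400, 1800, by = 25),
                        seed = 11)
  expect_equal(nrow(co), 400)
  expect_equal(length(unique(co$patient_id)), 10)
  expect_equal(as.vector(table(co$patient_id)[patient_order(co)]), counts)
  expect_equal(co$label[!duplicated(co$patient_id)], as.integer(labels))

  co2 <- generate_cohort(counts, labels, grid = seq(400, 1800, by = 25),
                         seed = 11)
  expect_identical(co, co2)    # bit-identical under the same seed

  co3 <- generate_cohort(counts, labels, grid = seq(400, 1800, by = 25),
                         seed = 12)
  expect_identical(co3$patient_id, co$patient_id)
  expect_false(identical(co3$spectrum[[1]]$intensity,
                         co$spectrum[[1]]$intensity))
})

test_that("zero noise and zero patient effect give the closed-form profile", {
  grid <- seq(400, 1800, by = 20)
  co <- generate_cohort(c(2, 2), c(0, 3), grid = grid, noise_sd = 0,
                        patient_effect_sd = 0, patient_scale_sd = 0,
                        patient_shift_sd = 0, seed = 5)
  profs <- default_class_profiles()
  expect_equal(co$spectrum[[1]]$intensity,
               profile_intensity(profs[["0"]], grid))
  expect_equal(co$spectrum[[3]]$intensity,
               profile_intensity(profs[["3"]], grid))
  # all spectra of one class identical in the degenerate setting
  expect_identical(co$spectrum[[1]], co$spectrum[[2]])
})

test_that("generator validates its configuration", {
  expect_error(generate_cohort(c(2, 2), c(0, 1, 2)), "equal length")
  expect_error(generate_cohort(c(2, 0), c(0, 1)), "positive")
  expect_error(generate_cohort(c(2, 2), c(0, 1),
                               profiles = default_class_profiles()["0"]),
               "no class profile")
})

test_that("reference cohort compositions match the study description", {
  co1 <- synthetic_dataset1(seed = 2, grid = seq(400, 1800, by = 25))
  expect_equal(nrow(co1), 400)
  expect_equal(co1$label[!duplicated(co1$patient_id)],
               c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(sum(co1$label == 0), 100)   # 32 + 31 + 37 EC spectra
  expect_equal(mean(co1$label == 0), 0.25) # EC is a quarter of the cohort

  co2 <- synthetic_dataset2(seed = 2, grid = seq(400, 1800, by = 25))
  expect_equal(nrow(co2), 10)
  expect_equal(length(unique(co2$patient_id)), 10)
  expect_equal(co2$label, c(1L, 2L, 2L, 1L, 1L, 2L, 0L, 3L, 3L, 0L))
  expect_length(intersect(co2$patient_id, co1$patient_id), 0)

  # wavenumber range of the default grid
  expect_equal(range(co1$spectrum[[1]]$wavenumber), c(400, 1800))
})

test_that("within-patient dispersion is below between-class dispersion", {
  co <- synthetic_dataset1(seed = 7, grid = seq(400, 1800, by = 25))
  m <- spectra_matrix(co)
  patient_means <- rowsum(m, co$patient_id) / as.vector(table(co$patient_id)[
    sort(unique(co$patient_id))])
  # mean distance of a spectrum to its own patient mean
  pm <- patient_means[match(co$patient_id, rownames(patient_means)), ]
  within <- mean(sqrt(rowSums((m - pm)^2)))
  class_means <- rowsum(m, co$label) / as.vector(table(co$label))
  d_class <- as.matrix(dist(class_means))
  between <- mean(d_class[upper.tri(d_class)])
  expect_lt(within, between)
})

test_that("class profiles round-trip through the YAML configuration", {
  profs <- default_class_profiles()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profiles(profs, path)
  back <- read_profiles(path)
  expect_equal(names(back), names(profs))
  for (lab in names(profs)) {
    expect_equal(as.data.frame(back[[lab]]$peaks),
                 as.data.frame(profs[[lab]]$peaks))
    expect_equal(back[[lab]]$baseline, profs[[lab]]$baseline)
  }
  # a generated cohort is identical under the round-tripped profiles
  g <- seq(400, 1800, by = 50)
  expect_identical(
    generate_cohort(c(2, 2), c(0, 1), profiles = back, grid = g, seed = 3),
    generate_cohort(c(2, 2), c(0, 1), profiles = profs, grid = g, seed = 3))
})
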