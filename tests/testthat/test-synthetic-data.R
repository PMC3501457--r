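test_that("tissue profiles cover the design: 9 tissues, blood/muscle with at most 4 extremes", {
  prof <- make_tissue_profiles(0)
  expect_length(prof, 9)
  targets <- vapply(prof, function(p) p$n_extremes_target, integer(1))
  expect_identical(sum(targets <= 4), 2L)
  expect_setequal(names(targets)[targets <= 4], c("blood", "muscle"))
  expect_true(all(targets[!names(targets) %in% c("blood", "muscle")] == 6L))
  for (p in prof) {
    expect_true(all(p$peak_centers > -1.8 & p$peak_centers < -0.7))
    expect_false(is.unsorted(p$peak_centers))
    expect_true(length(p$peak_centers) %in% c(3L, 4L))
    expect_identical(length(p$peak_centers), length(p$peak_heights))
    expect_identical(length(p$peak_centers), length(p$peak_widths))
  }
  alphas <- vapply(prof, function(p) p$segment_alpha, numeric(1))
  betas <- vapply(prof, function(p) p$segment_beta, numeric(1))
  expect_identical(anyDuplicated(alphas), 0L)
  expect_identical(anyDuplicated(betas), 0L)
})

test_that("profiles are a deterministic function of the seed", {
  expect_identical(make_tissue_profiles(0), make_tissue_profiles(0))
  a <- make_tissue_profiles(3)$liver
  b <- make_tissue_profiles(4)$liver
  expect_false(identical(a$peak_centers, b$peak_centers))
})

test_that("noise-free curves have exactly the target number of extremes (exhaustive scan)", {
  for (p in make_tissue_profiles(0)) {
    cv <- generate_voltammogram(p)
    bf <- brute_extremes(cv$currents)
    expect_identical(nrow(bf), as.integer(p$n_extremes_target))
  }
})

test_that("generated curves respect the acquisition grid contract", {
  p <- make_tissue_profiles(0)$spleen
  cv <- generate_voltammogram(p, subject_offset = 0.05,
                              replicate_noise_sd = 0.01, rng = 11)
  expect_length(cv$currents, 518)
  expect_equal(cv$potentials, potential_grid(518), tolerance = 1e-12)
  cv2 <- generate_voltammogram(p, n_points = 64, window = c(-1.6, -0.8))
  expect_length(cv2$currents, 64)
  expect_error(generate_voltammogram(p, replicate_noise_sd = -1), ">= 0")
})

test_that("amplitude-perturbed replicates fit on the tissue line q = alpha k + beta", {
  p <- make_tissue_profiles(0)$brain
  for (g in c(-0.08, 0.05, 0.12)) {
    f <- curve_segment_fit(generate_voltammogram(p, subject_offset = g))
    expect_lt(abs(f$q - (p$segment_alpha * f$k + p$segment_beta)), 1e-8)
  }
  # an explicit vertical family offset moves q off the line by that amount
  f2 <- curve_segment_fit(generate_voltammogram(p, family_noise = 0.02))
  expect_equal(f2$q - (p$segment_alpha * f2$k + p$segment_beta), 0.02,
               tolerance = 1e-8)
})

test_that("dataset generation honours the design counts and outlier flags", {
  ds <- fixture_dataset()
  expect_identical(n_curves(ds), 360L)
  expect_identical(nrow(default_outlier_flags()), 8L)
  # corrupted curves are amplitude-collapsed and therefore tiny
  rng <- vapply(ds$curves, function(cv) diff(range(cv$currents)), numeric(1))
  expect_identical(sum(rng < 0.3), 8L)

  small <- generate_dataset(
    dataset_spec(n_subjects = 1, n_replicates = 1, outlier_flags = NULL),
    fixture_profiles())
  expect_identical(n_curves(small), 9L)
})

test_that("dataset generation is deterministic and validates its inputs", {
  spec <- dataset_spec(seed = 5, n_subjects = 2, n_replicates = 2,
                       outlier_flags = NULL)
  prof <- make_tissue_profiles(5)
  expect_identical(generate_dataset(spec, prof), generate_dataset(spec, prof))
  expect_error(generate_dataset(spec, prof[1:3]), "n_tissues")
  bad <- dataset_spec(outlier_flags = data.frame(
    tissue = "liver", subject = "r99", replicate = "1"))
  expect_error(generate_dataset(bad, make_tissue_profiles(1)),
               "do not exist")
})
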