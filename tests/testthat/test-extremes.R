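test_that("differentiate is the zero-padded first difference and is inverted by prefix sums", {
  expect_identical(differentiate(rep(3, 5)), rep(0, 5))
  expect_identical(differentiate(c(0, 1, 3)), c(0, 1, 2))
  expect_error(differentiate(1), "length >= 2")
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- random_signal()
      expect_equal(cumsum(differentiate(x)) + x[1], x, tolerance = 1e-12)
    }
  })
})

test_that("sign_normalize maps zero upward and only emits +/- 0.5", {
  expect_identical(sign_normalize(c(-1, 0, 2)), c(-0.5, 0.5, 0.5))
  expect_identical(sign_normalize(c(3, 0.1)), c(0.5, 0.5))
  withr::with_seed(2, {
    out <- sign_normalize(rnorm(100))
    expect_true(all(out %in% c(-0.5, 0.5)))
  })
})

test_that("find_extremes matches the brute-force neighbour oracle, ties included", {
  withr::with_seed(3, {
    for (i in 1:300) {
      x <- random_signal(sample(10:120, 1))
      got <- find_extremes(x)
      want <- brute_extremes(x)
      expect_identical(got$position, want$position)
      expect_identical(got$kind, want$kind)
    }
  })
})

test_that("find_extremes handles canonical shapes", {
  # single bump: one maximum
  x <- exp(-(seq(-3, 3, length.out = 101))^2)
  e <- find_extremes(x)
  expect_identical(nrow(e), 1L)
  expect_identical(e$kind, "max")
  expect_identical(e$position, 51L)
  # noise-free six-extreme synthetic curve: alternating kinds
  cv <- generate_voltammogram(fixture_profiles()$liver)
  e6 <- find_extremes(cv)
  expect_identical(nrow(e6), 6L)
  expect_true(all(e6$kind[-1] != e6$kind[-6]))
  # endpoints are never extremes
  expect_identical(nrow(find_extremes(c(5, 1, 2, 3, 4))), 1L)
  expect_true(all(find_extremes(c(5, 1, 2, 3, 4))$position %in% 2:4))
})

test_that("merge_close_extremes removes the weaker of close pairs and restores alternation", {
  x <- c(numeric(299), 2, seq(0, -1, length.out = 21))  # spike then decay
  x[10] <- 1; x[12] <- -1
  e <- find_extremes(x)
  expect_identical(e$position, c(10L, 12L, 300L))
  m <- merge_close_extremes(e, min_distance = 5)
  expect_identical(nrow(m), 2L)
  expect_true(m$position[1] %in% 10:12)
  expect_identical(m$position[2], 300L)
  expect_true(all(m$kind[-1] != m$kind[-nrow(m)]))
})

test_that("merge_close_extremes is idempotent, gap-safe and a no-op at distance 1", {
  withr::with_seed(4, {
    for (i in 1:40) {
      x <- random_signal(150)
      e <- find_extremes(x)
      expect_identical(merge_close_extremes(e, 1), e)
      m <- merge_close_extremes(e, 7)
      if (nrow(m) > 1) expect_true(all(diff(m$position) >= 7))
      expect_identical(merge_close_extremes(m, 7), m)
    }
  })
})

test_that("name_peaks assigns the six named extremes on a liver-like curve", {
  cv <- generate_voltammogram(fixture_profiles()$liver)
  pk <- name_peaks(merge_close_extremes(find_extremes(cv), 5))
  for (nm in c("rs2co", "cat1", "cat2", "max1", "max2", "max3"))
    expect_false(is.null(pk[[nm]]))
  expect_lt(pk$cat2$potential, pk$cat1$potential)
  expect_lt(pk$cat1$potential, pk$rs2co$potential)
  w <- default_peak_windows()
  for (nm in c("rs2co", "cat1", "cat2", "max1", "max2", "max3")) {
    expect_gt(pk[[nm]]$potential, w[[nm]]$lo)
    expect_lte(pk[[nm]]$potential, w[[nm]]$hi)
  }
})

test_that("name_peaks leaves co1 empty on muscle-like curves but can assign a real Co1", {
  cv <- generate_voltammogram(fixture_profiles()$muscle)
  pk <- name_peaks(merge_close_extremes(find_extremes(cv), 5))
  expect_null(pk$co1)
  # a curve with a genuine Co1 dip: strong bump near -0.85 V
  cv2 <- toy_curve(centers = c(-1.50, -1.39, -1.27, -0.85),
                   heights = c(0.7, 0.4, 0.25, 0.30),
                   widths = c(0.035, 0.03, 0.03, 0.04))
  pk2 <- name_peaks(merge_close_extremes(find_extremes(cv2), 5))
  expect_false(is.null(pk2$co1))
  expect_gt(pk2$co1$potential, -0.95)
  expect_lte(pk2$co1$potential, -0.70)
})

test_that("name_peaks on an empty extreme set leaves every name empty", {
  e <- find_extremes(seq(10, 1))      # monotone: no extremes
  expect_identical(nrow(e), 0L)
  pk <- name_peaks(e)
  expect_true(all(vapply(pk, is.null, logical(1))))
})

test_that("nested same-kind windows are a configuration error", {
  w <- default_peak_windows()
  w$cat1$lo <- -1.63; w$cat1$hi <- -1.40   # now fully contains cat2
  e <- find_extremes(c(1, 0, 1))
  expect_error(name_peaks(e, w), "configuration error")
})

test_that("outlier flagging spots a collapsed replicate and honours manual flags", {
  p <- fixture_profiles()$heart
  good <- lapply(1:4, function(i)
    generate_voltammogram(p, replicate_noise_sd = 0.003, rng = i,
                          replicate = as.character(i)))
  collapsed <- generate_voltammogram(p, replicate = "5")
  collapsed$currents <- collapsed$currents * 0.05
  flags <- flag_outlier_replicates(c(good, list(collapsed)))
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  identical5 <- lapply(1:5, function(i)
    generate_voltammogram(p, replicate = as.character(i)))
  expect_identical(flag_outlier_replicates(identical5), rep(FALSE, 5))

  manual <- flag_outlier_replicates(c(good, list(collapsed)),
                                    manual = c("2", "3"))
  expect_identical(manual, c(FALSE, TRUE, TRUE, FALSE, FALSE))

  expect_warning(out <- flag_outlier_replicates(good[1:2]), "fewer than 3")
  expect_identical(out, c(FALSE, FALSE))
})

test_that("curated cleaning removes exactly the corrupted design cells", {
  cl <- fixture_cleaned()
  expect_identical(unname(cl$report),
                   c(360L, 8L, 352L))
  fl <- merge(cl$flagged, fixture_spec()$outlier_flags)
  expect_identical(nrow(fl), 8L)
})
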