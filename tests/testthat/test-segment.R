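test_that("find_inflection locates the zero of the second difference", {
  p <- potential_grid(101)
  t <- seq_along(p) - 51                       # cubic centred at sample 51
  cv <- voltammogram(p, (t / 20)^3, "toy", "s", "1")
  expect_identical(find_inflection(cv, c(20, 80)), 51L)
  # strictly convex segment: no sign change
  cv2 <- voltammogram(p, (t / 20)^2, "toy", "s", "1")
  expect_error(find_inflection(cv2, c(20, 80)), "no inflection")
  expect_error(find_inflection(cv, c(80, 20)), "acquisition order")
})

test_that("noise-free synthetic inflections match the generator's record within 2 samples", {
  for (nm in c("liver", "spleen", "blood")) {
    pr <- fixture_profiles()[[nm]]
    f <- curve_segment_fit(generate_voltammogram(pr))
    expect_lte(abs(f$inflection_index - pr$inflection_index), 2)
    expect_gt(f$inflection_potential, -1.65)
    expect_lt(f$inflection_potential, -1.50)
  }
})

test_that("fit_line_at_inflection recovers exact lines over m = 11 points", {
  p <- potential_grid(100)
  cv <- voltammogram(p, 2 * p + 3, "toy", "s", "1")
  f <- fit_line_at_inflection(cv, 50, halfwidth = 5)
  expect_equal(f$k, 2, tolerance = 1e-10)
  expect_equal(f$q, 3, tolerance = 1e-10)
  expect_identical(f$m, 11L)
  expect_lt(f$rms, 1e-10)
  # a symmetric cubic perturbation about the window centre leaves the
  # central slope untouched (odd function, orthogonal to the intercept)
  centre <- p[50]
  pert <- (p - centre)^3 * 50
  f2 <- fit_line_at_inflection(
    voltammogram(p, 2 * p + 3 + pert, "toy", "s", "1"), 50, 5)
  d <- (p[45:55] - centre)
  k_expect <- 2 + 50 * sum(d^3 * d) / sum(d^2)   # closed-form OLS slope
  expect_equal(f2$k, k_expect, tolerance = 1e-8)
  expect_equal(f2$q, 3 - (k_expect - 2) * centre, tolerance = 1e-8)
  expect_error(fit_line_at_inflection(cv, 3, 5), "out of curve bounds")
})

test_that("fit_tissue_family recovers fabricated exact families", {
  fits <- lapply(c(1, 2, 4, 7), function(k)
    structure(list(k = k, q = 0.5 * k + 2, tissue = "toy"),
              class = "segment_fit"))
  fam <- fit_tissue_family(fits)
  expect_equal(fam$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fam$beta, 2, tolerance = 1e-12)
  expect_equal(unname(fam$intersection), c(-0.5, 2), tolerance = 1e-12)
  expect_identical(fam$intersection[["x"]], -fam$alpha)
  expect_identical(fam$intersection[["y"]], fam$beta)
  expect_error(fit_tissue_family(fits[1:2]), "at least 3")
  same_k <- lapply(1:4, function(i)
    structure(list(k = 2, q = 3, tissue = "toy"), class = "segment_fit"))
  expect_error(fit_tissue_family(same_k), "degenerate")
})

test_that("zero-noise families share the intersection point to 1e-8", {
  for (nm in c("kidney", "heart")) {
    pr <- fixture_profiles()[[nm]]
    fits <- lapply(seq(-0.12, 0.12, length.out = 10), function(g)
      curve_segment_fit(generate_voltammogram(pr, subject_offset = g)))
    fam <- fit_tissue_family(fits)
    for (f in fits)
      expect_lt(abs(f$q - (fam$alpha * f$k + fam$beta)), 1e-8)
    expect_equal(fam$alpha, pr$segment_alpha, tolerance = 1e-6)
    expect_equal(fam$beta, pr$segment_beta, tolerance = 1e-6)
    # the common point lies in the vicinity of the inflection
    expect_lt(abs(fam$intersection["x"] -
                    potential_grid()[pr$inflection_index]), 0.02)
  }
})

test_that("correlation of -alpha with concentration behaves at the limits", {
  fam <- function(a, t) structure(list(tissue = t, alpha = a, beta = 1,
                                       intersection = c(x = -a, y = 1)),
                                  class = "tissue_line_family")
  fams <- Map(fam, c(-1, -2, -3, -4), c("a", "b", "c", "d"))
  lv <- c(a = 10, b = 20, c = 30, d = 40)
  expect_equal(correlate_alpha_with_level(fams, lv), 1, tolerance = 1e-12)
  expect_equal(correlate_alpha_with_level(fams, -lv + 100), -1,
               tolerance = 1e-12)
  expect_error(correlate_alpha_with_level(fams[1:2], lv), "at least 3")
  expect_error(correlate_alpha_with_level(fams, lv[1:3]), "missing")
  # shuffled levels: correlation collapses on average
  withr::with_seed(30, {
    many <- Map(fam, rnorm(30), paste0("t", 1:30))
    lvl <- stats::setNames(vapply(many, function(f) -f$alpha, numeric(1)) * 5 +
                             rnorm(30, 0, 0.1), paste0("t", 1:30))
    expect_gt(correlate_alpha_with_level(many, lvl), 0.99)
    rs <- replicate(200, correlate_alpha_with_level(
      many, stats::setNames(sample(lvl), names(lvl))))
    expect_lt(median(abs(rs)), 0.2)
    expect_lt(max(abs(rs)), 0.8)
  })
})
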