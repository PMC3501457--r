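test_that("feature tables have the documented shapes and exclusions", {
  w32 <- fixture_table("wavelet32")
  expect_identical(nrow(w32), 352L)
  expect_length(attr(w32, "feature_cols"), 32L)
  expect_identical(attr(w32, "feature_cols")[1], "w5coef0")
  expect_identical(length(unique(w32$tissue)), 9L)
  expect_false(anyNA(w32))

  m3 <- fixture_table("minima3")
  expect_identical(nrow(m3), 275L)
  expect_length(attr(m3, "feature_cols"), 6L)
  expect_identical(length(unique(m3$tissue)), 7L)
  expect_false(any(c("blood", "muscle") %in% m3$tissue))

  e6 <- fixture_table("extremes6")
  expect_identical(nrow(e6), 275L)
  expect_length(attr(e6, "feature_cols"), 12L)

  one <- brdicka_dataset(list(generate_voltammogram(fixture_profiles()$liver)))
  t1 <- build_feature_table(one, "minima3")
  expect_identical(dim(t1), c(1L, 9L))   # 3 labels + 6 features
  expect_error(build_feature_table(one, "nope"))
})

test_that("a perfectly separating feature yields a depth-1 tree with full training accuracy", {
  df <- data.frame(tissue = rep(c("a", "b"), each = 12),
                   f = c(rnorm(12, 0, 0.1), rnorm(12, 5, 0.1)),
                   subject = "s", replicate = "1")
  tab <- structure(df, class = c("feature_table", "data.frame"),
                   feature_cols = "f", mode = "toy")
  tree <- induce_tree(tab, minimal_leaf_size = 10)
  expect_identical(nrow(tree$rpart$frame), 3L)   # root + two leaves
  expect_identical(predict_tissue(tree, tab), df$tissue)
  expect_true(all(leaf_sizes(tree) >= 10))
})

test_that("tree induction respects the minimal leaf size and purity stopping rules", {
  w32 <- fixture_table("wavelet32")
  tree <- induce_tree(w32, minimal_leaf_size = 10)
  expect_true(all(leaf_sizes(tree) >= 10))
  # pure single-class table: a single leaf predicting that class
  sub <- w32[w32$tissue == "liver", ]
  attr(sub, "feature_cols") <- attr(w32, "feature_cols")
  class(sub) <- class(w32)
  pure <- induce_tree(sub)
  expect_length(leaf_sizes(pure), 1L)
  expect_identical(unique(predict_tissue(pure, sub)), "liver")
  empty <- w32[0, ]
  attr(empty, "feature_cols") <- attr(w32, "feature_cols")
  class(empty) <- class(w32)
  expect_error(induce_tree(empty), "empty")
})

test_that("with minimal leaf size 1 a tree separates any duplicate-free table perfectly", {
  withr::with_seed(20, {
    df <- data.frame(tissue = sample(rep(c("a", "b", "c"), each = 6)),
                     f1 = rnorm(18), f2 = rnorm(18),
                     subject = "s", replicate = "1")
    tab <- structure(df, class = c("feature_table", "data.frame"),
                     feature_cols = c("f1", "f2"), mode = "toy")
    tree <- induce_tree(tab, minimal_leaf_size = 1)
    expect_identical(mean(predict_tissue(tree, tab) == df$tissue), 1)
  })
})

test_that("stratified folds keep class proportions within one instance", {
  w32 <- fixture_table("wavelet32")
  res <- cross_validate(w32, folds = 10, seed = 99)
  # reconstruct fold sizes per class from the internal assignment
  folds <- voltfinger:::stratified_folds(w32$tissue, 10, 99)
  tab <- table(w32$tissue, folds)
  for (cl in rownames(tab))
    expect_lte(diff(range(tab[cl, ])), 1)
  expect_identical(sum(res$confusion), 352L)
})

test_that("cross-validation is deterministic given the seed and errors on small classes", {
  m3 <- fixture_table("minima3")
  a <- cross_validate(m3, seed = 5)
  b <- cross_validate(m3, seed = 5)
  expect_identical(a, b)
  c2 <- cross_validate(m3, seed = 6)
  expect_false(identical(a$confusion, c2$confusion) &&
                 identical(a$fold_accuracies, c2$fold_accuracies))

  small <- m3[m3$tissue != "liver" | seq_len(nrow(m3)) %in% which(m3$tissue == "liver")[1:5], ]
  attr(small, "feature_cols") <- attr(m3, "feature_cols")
  class(small) <- class(m3)
  expect_error(cross_validate(small, folds = 10), "liver")
})

test_that("confusion metrics follow the row-precision / column-recall contract", {
  m <- diag(5L) * 7L
  met <- confusion_metrics(m)
  expect_true(all(met$precision == 100))
  expect_true(all(met$recall == 100))
  expect_identical(met$accuracy, 100)
  m2 <- matrix(c(8L, 2L, 0L, 0L), 2, 2)  # row 2 predicts nothing correctly
  met2 <- confusion_metrics(m2)
  expect_equal(unname(met2$precision), c(100, 0))
  expect_equal(unname(met2$recall), c(80, NaN))
  expect_error(confusion_metrics(matrix(1:6, 2, 3)), "square")
  expect_error(confusion_metrics(matrix(c(1, -1, 0, 2), 2)), "non-negative")
})

test_that("top-level structure groups tissues as the curve-shape design intends", {
  w32 <- fixture_table("wavelet32")
  tree <- induce_tree(w32)
  # evaluate the root split: every tissue must fall wholly on one side, and
  # the high-amplitude group must separate from the rest
  fr <- tree$rpart$frame
  rootvar <- as.character(fr$var[1])
  cut <- tree$rpart$splits[1, "index"]
  side <- ifelse(w32[[rootvar]] < cut, "L", "R")
  tab <- table(w32$tissue, side)
  expect_true(all(apply(tab, 1, min) == 0))  # no tissue split across sides
  g1 <- c("liver", "kidney", "gonad", "brain")
  side_of <- apply(tab, 1, function(r) colnames(tab)[which.max(r)])
  expect_identical(length(unique(side_of[g1])), 1L)
  expect_false(unique(side_of[g1]) %in% side_of[setdiff(rownames(tab), g1)])
})
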