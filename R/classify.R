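#' Build a feature table for classification
#'
#' Three attribute sets describe each curve. `minima3`: potential and
#' current of the three named catalytic minima RS2Co, Cat1 and Cat2 (6
#' columns). `extremes6`: potential and current of all six named extremes,
#' the three minima plus Max1-Max3 (12 columns). `wavelet32`: the 32
#' level-5 Haar step attributes of the truncated 512-sample curve. For the
#' extreme-based modes blood and muscle curves are excluded (they do not
#' reach six extremes), and any further curve lacking a required named peak
#' is dropped with a message stating the count.
#'
#' @param dataset a (cleaned) [brdicka_dataset()].
#' @param mode `"minima3"`, `"extremes6"` or `"wavelet32"`.
#' @param windows,min_distance extreme naming parameters.
#' @param level wavelet level for `wavelet32` (default 5).
#' @return a `feature_table`: data frame with label columns `tissue`,
#'   `subject`, `replicate` and the feature columns (attribute
#'   `feature_cols`); no missing values.
#' @export
build_feature_table <- function(dataset,
                                mode = c("wavelet32", "minima3", "extremes6"),
                                windows = default_peak_windows(),
                                min_distance = 5, level = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "brdicka_dataset"))
  curves <- dataset$curves
  if (mode %in% c("minima3", "extremes6")) {
    keep <- vapply(curves, function(cv)
      !(cv$tissue %in% c("blood", "muscle")), logical(1))
    curves <- curves[keep]
    need <- if (mode == "minima3") c("rs2co", "cat1", "cat2")
            else c("rs2co", "cat1", "cat2", "max1", "max2", "max3")
    rows <- lapply(curves, function(cv) {
      pk <- name_peaks(merge_close_extremes(find_extremes(cv), min_distance),
                       windows)
      if (any(vapply(pk[need], is.null, logical(1)))) return(NULL)
      vals <- unlist(lapply(pk[need], function(x)
        c(x$potential, x$value)), use.names = FALSE)
      stats::setNames(vals, paste0(rep(need, each = 2),
                                   c("_potential", "_current")))
    })
    missing <- vapply(rows, is.null, logical(1))
    if (any(missing))
      message(sum(missing), " curve(s) lacking a required named peak excluded")
    curves <- curves[!missing]
    feat <- do.call(rbind, rows[!missing])
  } else {
    feat <- t(vapply(curves, function(cv)
      wavelet_attributes(cv, level)$coefs, numeric(2^level)))
  }
  lab <- data.frame(
    tissue = vapply(curves, function(cv) cv$tissue, character(1)),
    subject = vapply(curves, function(cv) cv$subject, character(1)),
    replicate = vapply(curves, function(cv) cv$replicate, character(1)),
    stringsAsFactors = FALSE)
  out <- cbind(lab, as.data.frame(feat))
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            feature_cols = colnames(feat), mode = mode)
}

#' Induce a decision tree with a minimal leaf size
#'
#' Greedy top-down induction of a classification tree on the feature table,
#' with an entropy (information) split criterion and the constraint that no
#' leaf may hold fewer than `minimal_leaf_size` training rows; the default
#' of 10 prevents leaves specialized to the five replicates of a single
#' subject. Built on `rpart` with complexity pruning disabled, so the
#' minimal-leaf rule is the only stopping criterion besides node purity.
#'
#' @param table a `feature_table` (>= 2 classes unless the table is pure).
#' @param minimal_leaf_size minimum rows per leaf (default 10).
#' @return object of class `tissue_tree` wrapping the `rpart` fit.
#' @export
induce_tree <- function(table, minimal_leaf_size = 10) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) == 0) stop("empty feature table")
  feats <- attr(table, "feature_cols")
  df <- as.data.frame(table)[, c("tissue", feats)]
  df$tissue <- factor(df$tissue)
  if (nlevels(df$tissue) == 1L) {          # pure table: a single leaf
    return(structure(list(rpart = NULL, constant = levels(df$tissue),
                          n = nrow(df), feature_cols = feats,
                          classes = levels(df$tissue),
                          minimal_leaf_size = minimal_leaf_size,
                          mode = attr(table, "mode")),
                     class = "tissue_tree"))
  }
  fit <- rpart::rpart(
    tissue ~ ., data = df, method = "class",
    parms = list(split = "information"),
    control = rpart::rpart.control(
      minsplit = max(2L, 2L * minimal_leaf_size),
      minbucket = minimal_leaf_size, cp = 0, xval = 0,
      maxcompete = 0, maxsurrogate = 0, maxdepth = 30))
  structure(list(rpart = fit, feature_cols = feats,
                 classes = levels(df$tissue),
                 minimal_leaf_size = minimal_leaf_size,
                 mode = attr(table, "mode")),
            class = "tissue_tree")
}

#' @export
print.tissue_tree <- function(x, ...) {
  cat(sprintf("<tissue_tree> mode %s, %d classes, minimal leaf size %d\n",
              x$mode %||% "?", length(x$classes), x$minimal_leaf_size))
  if (is.null(x$rpart)) cat("  single leaf:", x$constant, "\n")
  else print(x$rpart)
  invisible(x)
}

#' Predict tissue labels from a fitted tree
#'
#' @param model a `tissue_tree`.
#' @param newdata data frame containing the model's feature columns.
#' @return character vector of predicted tissue labels.
#' @export
predict_tissue <- function(model, newdata) {
  stopifnot(inherits(model, "tissue_tree"))
  if (is.null(model$rpart))
    return(rep(model$constant, nrow(as.data.frame(newdata))))
  miss <- setdiff(model$feature_cols, colnames(newdata))
  if (length(miss))
    stop("newdata lacks feature columns: ", paste(miss, collapse = ", "))
  as.character(predict(model$rpart,
                       newdata = as.data.frame(newdata)[model$feature_cols],
                       type = "class"))
}

#' Training-row count of every leaf of a tree
#'
#' @param model a `tissue_tree`.
#' @return integer vector of leaf sizes.
#' @export
leaf_sizes <- function(model) {
  if (is.null(model$rpart)) return(model$n)
  fr <- model$rpart$frame
  fr$n[fr$var == "<leaf>"]
}

# deterministic stratified fold assignment: within each class, indices are
# shuffled and dealt round-robin with a rotating starting fold, so fold
# class counts differ by at most one instance
stratified_folds <- function(classes, folds, seed) {
  assignment <- integer(length(classes))
  withr::with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      f <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      assignment[idx] <- f
      offset <- (offset + length(idx)) %% folds
    }
  })
  assignment
}

#' Stratified k-fold cross-validation of the decision tree
#'
#' Splits the table into `folds` disjoint subsets stratified by tissue
#' (each fold keeps the class proportions of the full table to within one
#' instance), trains a tree on the complement of each fold and pools all
#' test predictions into one confusion matrix with predicted classes as
#' rows and true classes as columns. Deterministic given `seed`.
#'
#' @param table a `feature_table`.
#' @param folds number of folds (default 10).
#' @param stratified must be `TRUE` (kept as an explicit contract).
#' @param seed integer seed for the fold assignment.
#' @param minimal_leaf_size passed to [induce_tree()].
#' @return object of class `cv_result`: list with the pooled `confusion`
#'   matrix, `fold_accuracies` (fractions), `accuracy_mean` and
#'   `accuracy_sd` (percent, sample sd over folds) and `n`.
#' @export
cross_validate <- function(table, folds = 10, stratified = TRUE, seed = 1,
                           minimal_leaf_size = 10) {
  stopifnot(inherits(table, "feature_table"), isTRUE(stratified))
  cls <- table$tissue
  counts <- table(cls)
  small <- names(counts)[counts < folds]
  if (length(small))
    stop("class smaller than the number of folds: ",
         paste(small, collapse = ", "))
  fold_id <- stratified_folds(cls, folds, seed)
  levels_all <- sort(unique(cls))
  confusion <- matrix(0L, length(levels_all), length(levels_all),
                      dimnames = list(predicted = levels_all,
                                      true = levels_all))
  acc <- numeric(folds)
  for (i in seq_len(folds)) {
    train <- table[fold_id != i, , drop = FALSE]
    test <- table[fold_id == i, , drop = FALSE]
    attr(train, "feature_cols") <- attr(table, "feature_cols")
    attr(train, "mode") <- attr(table, "mode")
    class(train) <- class(table)
    model <- induce_tree(train, minimal_leaf_size)
    pred <- predict_tissue(model, test)
    for (j in seq_len(nrow(test)))
      confusion[pred[j], test$tissue[j]] <-
        confusion[pred[j], test$tissue[j]] + 1L
    acc[i] <- mean(pred == test$tissue)
  }
  structure(
    list(confusion = confusion, fold_accuracies = acc,
         accuracy_mean = 100 * mean(acc),
         accuracy_sd = 100 * stats::sd(acc),
         n = nrow(table), folds = folds, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d curves, %d-fold CV: accuracy %.2f%% +/- %.2f%%\n",
              x$n, x$folds, x$accuracy_mean, x$accuracy_sd))
  invisible(x)
}

#' Precision, recall and accuracy from a confusion matrix
#'
#' With predicted classes as rows and true classes as columns:
#' `precision(c) = M[c, c] / rowsum(c)`, `recall(c) = M[c, c] / colsum(c)`,
#' overall accuracy `trace / total`, all in percent. An empty row or column
#' yields `NaN` for the corresponding metric.
#'
#' @param confusion square non-negative integer matrix (rows = predicted).
#' @return list with `precision`, `recall` (named vectors, percent) and
#'   `accuracy` (percent).
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion matrix must be non-negative")
  d <- diag(confusion)
  list(precision = 100 * d / rowSums(confusion),
       recall = 100 * d / colSums(confusion),
       accuracy = 100 * sum(d) / sum(confusion))
}
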