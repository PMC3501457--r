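#!/usr/bin/env Rscript
# Step 3: decision-tree classification under stratified 10-fold CV.
#
# Trees are induced with minimal leaf size 10 (so no leaf can specialize to
# one subject's five replicates) on each of the three attribute sets, and
# evaluated by stratified 10-fold cross-validation with a pooled confusion
# matrix (predicted tissues in rows, true in columns). The expected picture:
# the three minima alone classify worst, adding the maxima helps, and the
# 32 wavelet attributes - which also cover blood and muscle - do best.

suppressPackageStartupMessages(library(voltfinger))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dataset <- read_curves("results/dataset.csv", "tidy-csv", n_points = 518)
spec <- dataset_spec(seed = seed)
cleaned <- clean_dataset(dataset, manual_flags = spec$outlier_flags,
                         auto = FALSE)$dataset

summary_rows <- list()
for (mode in c("minima3", "extremes6", "wavelet32")) {
  tab <- build_feature_table(cleaned, mode)
  res <- cross_validate(tab, folds = 10,
                        seed = derive_seed(seed, paste0("cv_", mode)))
  met <- confusion_metrics(res$confusion)
  cat(sprintf("%-9s (%3d curves, %d tissues): accuracy %.2f%% +/- %.2f%%\n",
              mode, res$n, nrow(res$confusion),
              res$accuracy_mean, res$accuracy_sd))
  write.csv(as.data.frame(res$confusion),
            sprintf("results/confusion_%s.csv", mode), quote = FALSE)
  write.csv(data.frame(class = names(met$precision),
                       precision_pct = round(met$precision, 2),
                       recall_pct = round(met$recall, 2)),
            sprintf("results/class_metrics_%s.csv", mode),
            row.names = FALSE, quote = FALSE)
  summary_rows[[mode]] <- data.frame(mode = mode, n = res$n,
                                     accuracy_mean_pct = round(res$accuracy_mean, 2),
                                     accuracy_sd_pct = round(res$accuracy_sd, 2))
}
write.csv(do.call(rbind, summary_rows), "results/cv_summary.csv",
          row.names = FALSE, quote = FALSE)

# one tree on the full wavelet table, as the deployable classifier
tab <- build_feature_table(cleaned, "wavelet32")
tree <- induce_tree(tab)
writeLines(capture.output(print(tree$rpart)), "results/tree_wavelet32.txt")
cat("\nfull-data wavelet tree written to results/tree_wavelet32.txt\n")
cat(sprintf("leaves: %d, smallest leaf: %d rows\n",
            length(leaf_sizes(tree)), min(leaf_sizes(tree))))

# which tissues share each side of the root split?
fr <- tree$rpart$frame
rootvar <- as.character(fr$var[1])
cut <- tree$rpart$splits[1, "index"]
side <- ifelse(tab[[rootvar]] < cut, "left", "right")
cat(sprintf("root split on %s at %.4f:\n", rootvar, cut))
for (s in c("left", "right"))
  cat(sprintf("  %s: %s\n", s,
              paste(sort(unique(tab$tissue[side == s])), collapse = ", ")))
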