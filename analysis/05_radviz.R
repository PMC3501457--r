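#!/usr/bin/env Rscript
# Step 5: RadViz projection of the wavelet attributes covering the
# Cat2 -> Max3 stretch.
#
# Each curve's four attributes w5coef24 ... w5coef27 are mapped to the
# weighted centroid of four circular anchors (min-max normalized over the
# whole dataset). Because the underlying curve stretch is close to linear
# and varies mostly in amplitude, each tissue's points line up; the first
# principal component share per tissue quantifies that.

suppressPackageStartupMessages(library(voltfinger))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dataset <- read_curves("results/dataset.csv", "tidy-csv", n_points = 518)
spec <- dataset_spec(seed = seed)
cleaned <- clean_dataset(dataset, manual_flags = spec$outlier_flags,
                         auto = FALSE)$dataset

tab <- build_feature_table(cleaned, "wavelet32")
pts <- project_wavelet_subset(tab)
write.csv(pts, "results/radviz_points.csv", row.names = FALSE, quote = FALSE)
cat(sprintf("projected %d curves onto 4 anchors (w5coef24..w5coef27)\n",
            nrow(pts)))

cat("\nper-tissue collinearity of the projected points:\n")
for (t in sort(unique(pts$tissue))) {
  xy <- as.matrix(pts[pts$tissue == t, c("x", "y")])
  pc <- stats::prcomp(xy)
  cat(sprintf("  %-7s PC1 variance share %.3f (n = %d)\n",
              t, pc$sdev[1]^2 / sum(pc$sdev^2), nrow(xy)))
}
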