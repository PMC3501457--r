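#!/usr/bin/env Rscript
# Step 4: the Cat2 -> Max3 segment and its per-tissue line families.
#
# Each curve's near-linear stretch between the Cat2 minimum and the last
# maximum Max3 is characterized by an OLS line y = k x + q over the m = 11
# samples centred on the inflection point. Within a tissue the (k, q)
# pairs are collinear, q = alpha k + beta, which means all that tissue's
# segment lines pass through the single point <-alpha, beta>; the
# intersection sits close to the inflection. Finally -alpha is correlated
# with the tissue metallothionein level.

suppressPackageStartupMessages(library(voltfinger))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dataset <- read_curves("results/dataset.csv", "tidy-csv", n_points = 518)
spec <- dataset_spec(seed = seed)
cleaned <- clean_dataset(dataset, manual_flags = spec$outlier_flags,
                         auto = FALSE)$dataset

seg <- dataset_segment_fits(cleaned)
write.csv(seg$fits, "results/segment_fits.csv", row.names = FALSE,
          quote = FALSE)
cat(sprintf("segment fits: %d curves, inflections in (%.3f, %.3f) V\n",
            nrow(seg$fits), min(seg$fits$inflection_potential),
            max(seg$fits$inflection_potential)))

fam_df <- do.call(rbind, lapply(seg$families, function(f)
  data.frame(tissue = f$tissue, alpha = f$alpha, beta = f$beta,
             intersection_x = f$intersection[1],
             intersection_y = f$intersection[2],
             r2 = f$r2, n = f$n)))
rownames(fam_df) <- NULL
write.csv(fam_df, "results/line_families.csv", row.names = FALSE,
          quote = FALSE)
cat("\nper-tissue line families q = alpha k + beta:\n")
print(fam_df, digits = 4)

r <- correlate_alpha_with_level(seg$families, mt_reference())
cat(sprintf("\ncorrelation of -alpha with tissue MT level: r = %.1f%%\n",
            100 * r))
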