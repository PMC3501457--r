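#!/usr/bin/env Rscript
# Step 1: simulate the study dataset.
#
# Nine rat tissues (liver, blood, kidney, brain, eye, spleen, heart, muscle,
# gonad), eight subjects, five replicate Brdicka-reaction voltammograms per
# (tissue, subject) cell: 360 curves of 518 samples over (-1.8, -0.7) V.
# Eight replicates (in six groups, rats r6 and r8) are corrupted to emulate
# failed measurements. Writes the dataset as tidy CSV for the later steps.

suppressPackageStartupMessages(library(voltfinger))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

spec <- dataset_spec(seed = seed)
profiles <- make_tissue_profiles(seed)
dataset <- generate_dataset(spec, profiles)

cat(sprintf("simulated %d curves (%d tissues x %d subjects x %d replicates), seed %d\n",
            n_curves(dataset), spec$n_tissues, spec$n_subjects,
            spec$n_replicates, seed))
cat(sprintf("corrupted cells: %d (%s mode)\n",
            nrow(spec$outlier_flags), spec$outlier_mode))

write_curves(dataset, "results/dataset.csv", "tidy-csv")
cat("wrote results/dataset.csv\n")

prof_df <- do.call(rbind, lapply(profiles, function(p)
  data.frame(tissue = p$tissue_name,
             n_extremes_target = p$n_extremes_target,
             has_co1 = p$has_co1,
             alpha = p$segment_alpha, beta = p$segment_beta)))
write.csv(prof_df, "results/profiles.csv", row.names = FALSE, quote = FALSE)
cat("wrote results/profiles.csv (per-tissue design truth, incl. line-family alpha/beta)\n")
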