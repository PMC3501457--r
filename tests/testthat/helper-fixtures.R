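# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture_spec <- function() {
  if (is.null(.fixtures$spec)) .fixtures$spec <- dataset_spec(seed = 1)
  .fixtures$spec
}

fixture_profiles <- function() {
  if (is.null(.fixtures$profiles))
    .fixtures$profiles <- make_tissue_profiles(1)
  .fixtures$profiles
}

fixture_dataset <- function() {
  if (is.null(.fixtures$dataset))
    .fixtures$dataset <- generate_dataset(fixture_spec(), fixture_profiles())
  .fixtures$dataset
}

# curated cleaning by the known corrupted cells (the study's cleaning route)
fixture_cleaned <- function() {
  if (is.null(.fixtures$cleaned))
    .fixtures$cleaned <- clean_dataset(fixture_dataset(),
                                       manual_flags = fixture_spec()$outlier_flags,
                                       auto = FALSE)
  .fixtures$cleaned
}

fixture_table <- function(mode) {
  key <- paste0("tab_", mode)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- suppressMessages(
      build_feature_table(fixture_cleaned()$dataset, mode))
  .fixtures[[key]]
}

# brute-force neighbour-comparison oracle for local extremes, with the tie
# rules equivalent to the differentiate/sign_normalize chain (zero difference
# counts as non-decreasing)
brute_extremes <- function(x) {
  n <- length(x)
  pos <- integer(0); kind <- character(0)
  for (e in seq_len(n - 2L) + 1L) {
    if (x[e] >= x[e - 1] && x[e] > x[e + 1]) {
      pos <- c(pos, e); kind <- c(kind, "max")
    } else if (x[e] < x[e - 1] && x[e] <= x[e + 1]) {
      pos <- c(pos, e); kind <- c(kind, "min")
    }
  }
  data.frame(position = pos, kind = kind, stringsAsFactors = FALSE)
}

# direct block-mean oracle for the wavelet step attributes
block_means_oracle <- function(x, n_blocks) {
  w <- length(x) / n_blocks
  vapply(seq_len(n_blocks), function(j) mean(x[((j - 1) * w + 1):(j * w)]),
         numeric(1))
}

# random test signals of mixed character: smooth walks, rough noise and
# tie-rich rounded walks
random_signal <- function(n = 80) {
  switch(sample(3, 1),
         cumsum(rnorm(n)),
         rnorm(n),
         round(cumsum(rnorm(n)), 1))
}

# minimal synthetic curve: Gaussian dips on a ramped exponential baseline,
# stored negated (catalytic peaks are minima)
toy_curve <- function(centers, heights, widths, amp = 1.5, tau = 0.13,
                      ramp = 0.35, n = 518, tissue = "toy",
                      subject = "s1", replicate = "1") {
  p <- potential_grid(n)
  u <- -p
  y <- amp * exp((u - 1.8) / tau) + ramp * (u - 0.7)
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(p - centers[i])^2 / (2 * widths[i]^2))
  voltammogram(p, -y, tissue, subject, replicate)
}
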