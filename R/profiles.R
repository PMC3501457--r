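#' Reference metallothionein levels per tissue
#'
#' Mean metallothionein content (micrograms per gram) used when relating the
#' line-family abscissa -alpha to tissue MT level. Kidney, liver, brain and
#' spleen are measured reference values; heart and muscle are reported only
#' as roughly half the level of the detoxifying organs, and the remaining
#' tissues carry synthetic plausible values chosen to respect that ordering.
#'
#' @return named numeric vector (micrograms per gram).
#' @export
mt_reference <- function() {
  c(liver = 48.7, blood = 30.0, kidney = 67.0, brain = 50.5, eye = 26.0,
    spleen = 41.5, heart = 24.0, muscle = 23.0, gonad = 27.0)
}

# Base per-tissue signal design. Amplitude bands encode the three shape
# groups the decision tree should discover: high-amplitude (liver, kidney,
# brain, gonad), low-amplitude four-extreme (blood, muscle) and
# mid-amplitude (heart, eye, spleen). Liver/kidney and heart/eye carry
# near-identical minima coordinates and differ mainly in the wall decay
# scale, so that classification from minima alone is genuinely harder than
# from the full curve shape. Cat2 centres loosely co-vary with MT level.
tissue_design <- function() {
  d <- list(
    #        amp    tau   ramp  co1_h rs2co_c  rs2co_h cat1_c  cat1_h cat2_c  cat2_h
    liver  = c(2.20, 0.120, 0.35, 0.018, -1.265, 0.28, -1.390, 0.42, -1.490, 0.85),
    blood  = c(0.55, 0.150, 0.30, 0.000, -1.280, 0.02, -1.395, 0.28, -1.524, 0.45),
    kidney = c(2.20, 0.135, 0.35, 0.016, -1.263, 0.27, -1.388, 0.44, -1.484, 0.88),
    brain  = c(1.90, 0.125, 0.35, 0.015, -1.285, 0.24, -1.400, 0.50, -1.500, 0.78),
    eye    = c(1.20, 0.140, 0.35, 0.012, -1.277, 0.21, -1.397, 0.32, -1.522, 0.53),
    spleen = c(1.00, 0.130, 0.35, 0.000, -1.250, 0.26, -1.380, 0.40, -1.508, 0.62),
    heart  = c(1.20, 0.125, 0.35, 0.012, -1.275, 0.20, -1.395, 0.33, -1.519, 0.55),
    muscle = c(0.48, 0.145, 0.30, 0.000, -1.270, 0.02, -1.385, 0.25, -1.536, 0.40),
    gonad  = c(1.75, 0.130, 0.35, 0.000, -1.240, 0.30, -1.370, 0.38, -1.516, 0.70))
  lapply(d, function(v) stats::setNames(v, c("amp", "tau", "ramp", "co1_h",
                                             "rs2co_c", "rs2co_h", "cat1_c",
                                             "cat1_h", "cat2_c", "cat2_h")))
}

#' Potential grid of the acquisition
#'
#' Equidistant potentials in acquisition order, from the least negative
#' (default -0.7 V) toward the most negative end of the window.
#'
#' @param n_points number of samples (default 518).
#' @param window potential window `c(low, high)` in volts
#'   (default c(-1.8, -0.7)).
#' @return numeric vector of strictly decreasing potentials.
#' @export
potential_grid <- function(n_points = 518, window = c(-1.8, -0.7)) {
  seq(max(window), min(window), length.out = n_points)
}

# Noise-free stored signal for a set of peak parameters. Stored currents are
# the negated plotted voltammogram, so catalytic peaks are local minima and
# the hydrogen-evolution wall plunges toward the most negative potential.
base_signal <- function(p, amp, tau, ramp, centers, heights, widths) {
  u <- -p
  baseline <- amp * exp((u - 1.8) / tau) + ramp * (u - 0.7)
  peaks <- 0
  for (i in seq_along(centers))
    peaks <- peaks + heights[i] * exp(-(p - centers[i])^2 / (2 * widths[i]^2))
  -(baseline + peaks)
}

profile_signal <- function(profile, p, shift = 0) {
  base_signal(p, profile$baseline_params["amplitude"],
              profile$baseline_params["decay"],
              profile$baseline_params["ramp"],
              profile$peak_centers + shift, profile$peak_heights,
              profile$peak_widths)
}

#' Build the nine synthetic tissue profiles
#'
#' Returns one profile per tissue (liver, blood, kidney, brain, eye, spleen,
#' heart, muscle, gonad). Blood and muscle have four local extremes; all
#' other tissues have six (three minima RS2Co/Cat1/Cat2 and three maxima).
#' Tissues carrying the occasional Co1 signal get a weak Co1 shoulder that
#' does not invert the monotone head of the curve. Each profile records its
#' line-family parameters: an affine pivot `(x = -segment_alpha,
#' y = segment_beta)` on the tangent of the base curve at its inflection
#' between Cat2 and Max3, about which subject and replicate amplitude
#' variation rotates the segment, so noise-free replicates produce segment
#' fits `(k, q)` lying exactly on `q = segment_alpha * k + segment_beta`.
#'
#' A small seeded jitter on centres, heights and baseline makes different
#' seeds emulate different laboratories while keeping every profile
#' deterministic given the seed.
#'
#' @param seed integer seed.
#' @return named list of `tissue_profile` objects.
#' @export
make_tissue_profiles <- function(seed = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  design <- tissue_design()
  p <- potential_grid()
  withr::with_seed(derive_seed(seed, "profiles"), {
    profiles <- lapply(names(design), function(tis) {
      d <- design[[tis]]
      has_co1 <- d["co1_h"] > 0
      centers <- c(d["rs2co_c"], d["cat1_c"], d["cat2_c"]) +
        pmin(pmax(stats::rnorm(3, 0, 0.002), -0.004), 0.004)
      heights <- c(d["rs2co_h"], d["cat1_h"], d["cat2_h"]) *
        (1 + stats::rnorm(3, 0, 0.03))
      widths <- c(if (tis %in% c("blood", "muscle")) 0.05 else 0.03,
                  0.03, 0.035)
      if (has_co1) {
        centers <- c(centers, -0.85)
        heights <- c(heights, d["co1_h"])
        widths <- c(widths, 0.06)
      }
      ord <- order(centers)                      # sorted, most negative first
      nms <- c("rs2co", "cat1", "cat2", if (has_co1) "co1")[ord]
      amp <- d["amp"] * (1 + stats::rnorm(1, 0, 0.03))
      tau <- d["tau"] * (1 + stats::rnorm(1, 0, 0.02))
      prof <- structure(
        list(tissue_name = tis,
             peak_centers = stats::setNames(unname(centers[ord]), nms),
             peak_heights = stats::setNames(unname(heights[ord]), nms),
             peak_widths = stats::setNames(unname(widths[ord]), nms),
             has_co1 = unname(has_co1),
             baseline_params = c(amplitude = unname(amp),
                                 decay = unname(tau),
                                 ramp = unname(d["ramp"])),
             n_extremes_target = if (tis %in% c("blood", "muscle")) 4L else 6L),
        class = "tissue_profile")
      # anchor the line family on the base curve's inflection tangent; the
      # pivot abscissa sits within ~4 mV of the inflection (off-grid, so
      # every tissue carries its own alpha)
      cv <- voltammogram(p, profile_signal(prof, p), tis, "base", "0")
      fit <- curve_segment_fit(cv)
      x_piv <- fit$inflection_potential + stats::runif(1, -0.004, 0.004)
      y_piv <- fit$k * x_piv + fit$q
      prof$segment_alpha <- -x_piv
      prof$segment_beta <- y_piv
      prof$inflection_index <- fit$inflection_index
      prof
    })
  })
  stats::setNames(profiles, names(design))
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("<tissue_profile> %s: %d peaks, %d extremes, alpha=%.4f beta=%.4f\n",
              x$tissue_name, length(x$peak_centers), x$n_extremes_target,
              x$segment_alpha, x$segment_beta))
  invisible(x)
}

# white noise smoothed with a Gaussian kernel (sd `kernel_sd` samples) and
# rescaled to the requested marginal sd; emulates the slow instrumental
# waves seen on non-smooth measured curves
smooth_noise <- function(n, sd, kernel_sd = 5) {
  if (sd == 0) return(numeric(n))
  half <- 3L * kernel_sd
  kern <- stats::dnorm(seq(-half, half), sd = kernel_sd)
  kern <- kern / sum(kern)
  w <- stats::rnorm(n + 2L * half)
  sm <- stats::filter(w, kern, sides = 2)
  sm <- as.numeric(sm[(half + 1L):(half + n)])
  sm / sqrt(sum(kern^2)) * sd
}

#' Generate one synthetic voltammogram
#'
#' The stored current is a monotone baseline plus bell-shaped catalytic
#' peaks (negated so that peaks are minima), scaled about the profile's
#' family pivot and perturbed by replicate-level effects:
#' `y_piv + G * (s0(shift) - y_piv) + family_noise + smooth noise`, where
#' `G = (1 + subject_offset) * (1 + replicate_amp)`. With all perturbations
#' at zero the curve has exactly `n_extremes_target` local extremes, and
#' with only amplitude perturbations the segment fit `(k, q)` lies exactly
#' on the profile's line `q = alpha k + beta`.
#'
#' @param profile a `tissue_profile`.
#' @param subject_offset relative amplitude offset of the subject (e.g.
#'   0.05 for +5%).
#' @param replicate_noise_sd standard deviation of the smooth measurement
#'   noise (current units, >= 0).
#' @param rng optional integer seed for this curve; if `NULL` the current
#'   RNG state is used.
#' @param replicate_amp relative amplitude offset of the replicate.
#' @param shift potential shift (V) applied to all peak centres.
#' @param family_noise vertical offset (current units) added to the whole
#'   curve; moves q off the family line by exactly this amount.
#' @param subject,replicate labels for the resulting curve.
#' @param n_points,window acquisition grid (defaults 518 samples over
#'   (-1.8, -0.7) V).
#' @return a [voltammogram()].
#' @export
generate_voltammogram <- function(profile, subject_offset = 0,
                                  replicate_noise_sd = 0, rng = NULL,
                                  replicate_amp = 0, shift = 0,
                                  family_noise = 0,
                                  subject = "s1", replicate = "1",
                                  n_points = 518, window = c(-1.8, -0.7)) {
  stopifnot(inherits(profile, "tissue_profile"))
  if (replicate_noise_sd < 0) stop("replicate_noise_sd must be >= 0")
  p <- potential_grid(n_points, window)
  build <- function() {
    s0 <- profile_signal(profile, p, shift = shift)
    g <- (1 + subject_offset) * (1 + replicate_amp)
    y <- profile$segment_beta + g * (s0 - profile$segment_beta) +
      family_noise + smooth_noise(length(p), replicate_noise_sd)
    voltammogram(p, y, profile$tissue_name, subject, replicate)
  }
  if (is.null(rng)) build() else withr::with_seed(as.integer(rng), build())
}

#' Default manual outlier design
#'
#' The eight corrupted measurements injected into the default dataset:
#' replicates of rats r6 and r8 in gonad, heart, blood and muscle, spread
#' over six (tissue, subject) groups so that the affected groups retain 3
#' or 4 usable curves.
#'
#' @return data frame with columns `tissue`, `subject`, `replicate`.
#' @export
default_outlier_flags <- function() {
  data.frame(
    tissue = c("gonad", "gonad", "gonad", "heart", "heart",
               "blood", "muscle", "muscle"),
    subject = c("r6", "r6", "r8", "r6", "r8", "r6", "r8", "r8"),
    replicate = c("1", "2", "3", "2", "4", "5", "1", "3"),
    stringsAsFactors = FALSE)
}

#' Dataset design specification
#'
#' Collects the design counts, acquisition grid, perturbation magnitudes
#' and outlier design of a synthetic dataset. Defaults reproduce the study
#' design: 9 tissues x 8 subjects x 5 replicates = 360 curves of 518
#' samples over (-1.8, -0.7) V with 8 corrupted replicates (~2%).
#'
#' @param n_tissues,n_subjects,n_replicates design counts.
#' @param n_points samples per curve.
#' @param potential_window potential window in volts.
#' @param outlier_flags data frame of (tissue, subject, replicate) cells to
#'   corrupt, or `NULL` for none.
#' @param seed master seed for the dataset.
#' @param subject_amp_sd,subject_shift_sd between-subject amplitude (relative)
#'   and peak-position (V) variability.
#' @param replicate_amp_sd,replicate_shift_sd within-subject counterparts.
#' @param noise_sd smooth measurement noise sd (current units).
#' @param family_noise_frac bound on the per-replicate vertical offset,
#'   drawn uniformly on +/- `family_noise_frac * |beta|` (default 1%).
#' @param outlier_mode `"collapse"` (amplitude collapse to 5%) or
#'   `"truncate"` (signal frozen after 60% of the sweep).
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_tissues = 9, n_subjects = 8, n_replicates = 5,
                         n_points = 518, potential_window = c(-1.8, -0.7),
                         outlier_flags = default_outlier_flags(), seed = 1,
                         subject_amp_sd = 0.08, subject_shift_sd = 0.0025,
                         replicate_amp_sd = 0.025, replicate_shift_sd = 0.002,
                         noise_sd = 0.003, family_noise_frac = 0.01,
                         outlier_mode = c("collapse", "truncate")) {
  outlier_mode <- match.arg(outlier_mode)
  stopifnot(n_tissues >= 1, n_subjects >= 1, n_replicates >= 1, n_points >= 8)
  structure(
    list(n_tissues = as.integer(n_tissues),
         n_subjects = as.integer(n_subjects),
         n_replicates = as.integer(n_replicates),
         n_points = as.integer(n_points),
         potential_window = potential_window,
         outlier_flags = outlier_flags, seed = seed,
         subject_amp_sd = subject_amp_sd, subject_shift_sd = subject_shift_sd,
         replicate_amp_sd = replicate_amp_sd,
         replicate_shift_sd = replicate_shift_sd,
         noise_sd = noise_sd, family_noise_frac = family_noise_frac,
         outlier_mode = outlier_mode),
    class = "dataset_spec")
}

corrupt_curve <- function(cv, mode) {
  n <- length(cv$currents)
  y <- cv$currents
  if (mode == "collapse") {
    y <- y * 0.05
  } else {
    cut <- floor(0.6 * n)
    y[(cut + 1L):n] <- y[cut]          # sweep dies: signal frozen mid-curve
  }
  voltammogram(cv$potentials, y, cv$tissue, cv$subject, cv$replicate)
}

#' Generate a full labelled dataset
#'
#' Draws subject- and replicate-level perturbations for every design cell
#' and builds the corresponding voltammograms; cells listed in
#' `spec$outlier_flags` are replaced by corrupted curves emulating a failed
#' measurement. The result is a pure function of `(spec, profiles)`.
#'
#' @param spec a [dataset_spec()].
#' @param profiles list of `tissue_profile`s; its length must equal
#'   `spec$n_tissues`.
#' @return a [brdicka_dataset()] of
#'   `n_tissues * n_subjects * n_replicates` curves.
#' @export
generate_dataset <- function(spec = dataset_spec(),
                             profiles = make_tissue_profiles(spec$seed)) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (length(profiles) != spec$n_tissues)
    stop("profile count (", length(profiles), ") != n_tissues (",
         spec$n_tissues, ")")
  tissues <- vapply(profiles, function(pr) pr$tissue_name, character(1))
  subjects <- paste0("r", seq_len(spec$n_subjects))
  replicates <- as.character(seq_len(spec$n_replicates))
  fl <- spec$outlier_flags
  if (!is.null(fl) && nrow(fl) > 0) {
    ok <- fl$tissue %in% tissues & fl$subject %in% subjects &
      fl$replicate %in% replicates
    if (!all(ok))
      stop("outlier_flags reference design cells that do not exist")
  }
  curves <- vector("list", spec$n_tissues * spec$n_subjects * spec$n_replicates)
  i <- 0L
  withr::with_seed(derive_seed(spec$seed, "dataset"), {
    for (pr in profiles) {
      for (s in subjects) {
        s_amp <- stats::rnorm(1, 0, spec$subject_amp_sd)
        s_shift <- stats::rnorm(1, 0, spec$subject_shift_sd)
        for (r in replicates) {
          r_amp <- stats::rnorm(1, 0, spec$replicate_amp_sd)
          r_shift <- stats::rnorm(1, 0, spec$replicate_shift_sd)
          fam <- stats::runif(1, -1, 1) * spec$family_noise_frac *
            abs(pr$segment_beta)     # bounded family noise, |eps| <= frac|beta|
          cv <- generate_voltammogram(
            pr, subject_offset = s_amp,
            replicate_noise_sd = spec$noise_sd, rng = NULL,
            replicate_amp = r_amp, shift = s_shift + r_shift,
            family_noise = fam, subject = s, replicate = r,
            n_points = spec$n_points, window = spec$potential_window)
          if (!is.null(fl) && nrow(fl) > 0 &&
              any(fl$tissue == pr$tissue_name & fl$subject == s &
                    fl$replicate == r))
            cv <- corrupt_curve(cv, spec$outlier_mode)
          i <- i + 1L
          curves[[i]] <- cv
        }
      }
    }
  })
  brdicka_dataset(curves,
                  provenance = sprintf("synthetic (seed %s)", spec$seed))
}
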