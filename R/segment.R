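#' Locate the inflection point between the Cat2 minimum and Max3
#'
#' Searches the open index interval between the Cat2 extreme and the Max3
#' extreme for a sign change of the discrete second difference
#' `x[j-1] - 2 x[j] + x[j+1]`. If several sign changes occur, the one with
#' the steepest first difference is taken. For realistic Brdicka curves the
#' inflection potential falls in roughly (-1.65, -1.5) V.
#'
#' @param curve a [voltammogram()].
#' @param between integer vector `c(cat2_index, max3_index)` in acquisition
#'   order (`max3_index > cat2_index`).
#' @return the inflection sample index.
#' @export
find_inflection <- function(curve, between) {
  stopifnot(inherits(curve, "voltammogram"), length(between) == 2)
  i0 <- as.integer(between[1]); i1 <- as.integer(between[2])
  if (i1 <= i0) stop("max3 index must follow cat2 index in acquisition order")
  x <- curve$currents
  js <- seq(max(i0 + 1L, 2L), min(i1 - 1L, length(x) - 1L))
  if (length(js) < 2) stop("no inflection: interval too short")
  d2 <- x[js - 1L] - 2 * x[js] + x[js + 1L]
  s <- sign(d2)
  cand <- js[s == 0]                               # exact zeros of the second difference
  flips <- which(s[-length(s)] * s[-1] < 0)        # strict sign changes
  if (length(flips) > 0) {
    nearer <- ifelse(abs(d2[flips + 1L]) < abs(d2[flips]), flips + 1L, flips)
    cand <- unique(c(cand, js[nearer]))
  }
  if (length(cand) == 0)
    stop("no inflection: second difference does not change sign")
  slope <- abs(x[cand + 1L] - x[cand - 1L]) / 2
  cand[which.max(slope)]
}

#' Fit a line to the neighbourhood of the inflection point
#'
#' Ordinary least squares of current on potential over the
#' `m = 2 * halfwidth + 1` samples centred on the inflection (5 points to
#' each side by default, m = 11).
#'
#' @param curve a [voltammogram()].
#' @param inflection inflection sample index.
#' @param halfwidth number of samples on each side (default 5).
#' @return object of class `segment_fit`: list with `inflection_index`,
#'   `inflection_potential`, slope `k` (current units per volt), intercept
#'   `q`, `m` and the fit residual RMS.
#' @export
fit_line_at_inflection <- function(curve, inflection, halfwidth = 5) {
  stopifnot(inherits(curve, "voltammogram"))
  inflection <- as.integer(inflection)
  n <- length(curve$currents)
  if (inflection - halfwidth < 1 || inflection + halfwidth > n)
    stop("fit window out of curve bounds")
  idx <- (inflection - halfwidth):(inflection + halfwidth)
  p <- curve$potentials[idx]
  y <- curve$currents[idx]
  fit <- stats::lm.fit(cbind(1, p), y)
  k <- unname(fit$coefficients[2])
  q <- unname(fit$coefficients[1])
  structure(
    list(inflection_index = inflection,
         inflection_potential = curve$potentials[inflection],
         k = k, q = q, m = length(idx),
         rms = sqrt(mean(fit$residuals^2)),
         tissue = curve$tissue, subject = curve$subject,
         replicate = curve$replicate),
    class = "segment_fit")
}

#' Inflection-anchored segment fit of one curve
#'
#' Full chain for a single voltammogram: detect and merge extremes, name
#' peaks, locate the inflection between Cat2 and Max3, and fit the m = 11
#' point line.
#'
#' @param curve a [voltammogram()].
#' @param windows peak windows (see [default_peak_windows()]).
#' @param min_distance merge threshold for [merge_close_extremes()].
#' @param halfwidth fit half-width (default 5).
#' @return a `segment_fit`.
#' @export
curve_segment_fit <- function(curve, windows = default_peak_windows(),
                              min_distance = 5, halfwidth = 5) {
  e <- merge_close_extremes(find_extremes(curve), min_distance)
  pk <- name_peaks(e, windows)
  if (is.null(pk$cat2) || is.null(pk$max3))
    stop("curve lacks a named Cat2 or Max3 extreme")
  infl <- find_inflection(curve, c(pk$cat2$position, pk$max3$position))
  fit_line_at_inflection(curve, infl, halfwidth)
}

#' Fit the per-tissue line family q = alpha * k + beta
#'
#' Regresses the intercepts q of a tissue's segment fits on their slopes k.
#' If q is (approximately) a linear function of k, every segment line
#' `y = k x + q = k (x + alpha) + beta` passes through the common point
#' `<-alpha, beta>`, which is returned as the family intersection.
#'
#' @param fits list of `segment_fit` objects from one tissue (>= 3).
#' @param tissue optional tissue label (taken from the fits if omitted).
#' @return object of class `tissue_line_family`: list with `tissue`,
#'   `alpha`, `beta`, `intersection` (c(x, y) = c(-alpha, beta)), `r2` and
#'   `n`.
#' @export
fit_tissue_family <- function(fits, tissue = NULL) {
  stopifnot(is.list(fits))
  if (length(fits) < 3)
    stop("need at least 3 segment fits for a line family")
  k <- vapply(fits, function(f) f$k, numeric(1))
  q <- vapply(fits, function(f) f$q, numeric(1))
  if (stats::sd(k) == 0)
    stop("degenerate family: all slopes k identical (vertical family)")
  fit <- stats::lm(q ~ k)
  alpha <- unname(stats::coef(fit)[2])
  beta <- unname(stats::coef(fit)[1])
  ss_tot <- sum((q - mean(q))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  if (is.null(tissue)) {
    tis <- unique(vapply(fits, function(f) f$tissue %||% "", character(1)))
    tissue <- if (length(tis) == 1) tis else paste(tis, collapse = "+")
  }
  structure(
    list(tissue = tissue, alpha = alpha, beta = beta,
         intersection = c(x = -alpha, y = beta), r2 = r2, n = length(fits)),
    class = "tissue_line_family")
}

#' @export
print.tissue_line_family <- function(x, ...) {
  cat(sprintf("<tissue_line_family> %s: alpha=%.5f beta=%.5f  intersection <%.5f, %.5f>  r2=%.4f (n=%d)\n",
              x$tissue, x$alpha, x$beta, x$intersection[1], x$intersection[2],
              x$r2, x$n))
  invisible(x)
}

#' Segment fits and line families for a whole dataset
#'
#' @param dataset a [brdicka_dataset()] (typically cleaned).
#' @param windows,min_distance,halfwidth passed to [curve_segment_fit()].
#' @return list with `fits` (data frame of per-curve k, q, inflection) and
#'   `families` (named list of `tissue_line_family`, tissues with >= 3
#'   usable fits).
#' @export
dataset_segment_fits <- function(dataset, windows = default_peak_windows(),
                                 min_distance = 5, halfwidth = 5) {
  fits <- list()
  for (cv in dataset$curves) {
    f <- tryCatch(curve_segment_fit(cv, windows, min_distance, halfwidth),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  df <- data.frame(
    tissue = vapply(fits, function(f) f$tissue, character(1)),
    subject = vapply(fits, function(f) f$subject, character(1)),
    replicate = vapply(fits, function(f) f$replicate, character(1)),
    inflection_potential = vapply(fits, function(f) f$inflection_potential, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    q = vapply(fits, function(f) f$q, numeric(1)),
    stringsAsFactors = FALSE)
  fam <- list()
  for (t in unique(df$tissue)) {
    sel <- which(df$tissue == t)
    if (length(sel) >= 3)
      fam[[t]] <- fit_tissue_family(fits[sel], tissue = t)
  }
  list(fits = df, families = fam)
}

#' Correlation between -alpha and tissue concentration levels
#'
#' Pearson correlation of the family intersection abscissa `-alpha` with a
#' per-tissue concentration (e.g. metallothionein level in micrograms per
#' gram).
#'
#' @param families list of `tissue_line_family` objects (>= 3 tissues).
#' @param levels named numeric vector of concentrations; names must cover
#'   the family tissues.
#' @return Pearson correlation coefficient (fraction, in \[-1, 1\]).
#' @export
correlate_alpha_with_level <- function(families, levels) {
  stopifnot(is.list(families))
  if (length(families) < 3)
    stop("need at least 3 tissues to correlate")
  tis <- vapply(families, function(f) f$tissue, character(1))
  if (!all(tis %in% names(levels)))
    stop("levels missing for: ",
         paste(setdiff(tis, names(levels)), collapse = ", "))
  neg_alpha <- vapply(families, function(f) -f$alpha, numeric(1))
  stats::cor(neg_alpha, as.numeric(levels[tis]))
}
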