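#' Truncate a 518-sample curve to 512 samples
#'
#' Drops the 6 samples nearest -0.7 V, i.e. the first 6 in acquisition
#' order, so that the length becomes 512 = 2^9 as required by the Haar
#' transform. Inputs whose length is already a power of 2 pass through
#' unchanged; any other length is an error.
#'
#' @param curve a [voltammogram()] or numeric current vector.
#' @return numeric vector of length 512 (or the untouched power-of-2 input).
#' @export
truncate_to_pow2 <- function(curve) {
  x <- if (inherits(curve, "voltammogram")) curve$currents else as.numeric(curve)
  n <- length(x)
  if (n == 518) return(x[7:518])
  if (n >= 2 && bitwAnd(n, n - 1L) == 0L) return(x)
  stop("expected a 518-sample curve (or a power-of-2 signal), got ", n)
}

block_means <- function(x, n_blocks) {
  colMeans(matrix(x, ncol = n_blocks))
}

#' Forward Haar Simple Wavelet transform (mean/difference form)
#'
#' Truncated Haar decomposition of a power-of-2 signal, in the mean-based
#' normalization: the first coefficient is the global mean of the signal;
#' each subsequent refinement coefficient is the difference between the mean
#' of a half-interval and the mean of its parent interval. At `level` k the
#' transform returns 2^k coefficients: the mean plus 2^k - 1 refinement
#' differences, which together determine the 2^k block means of the signal.
#'
#' @param x numeric signal whose length is a power of 2.
#' @param level decomposition level k, 1 <= k <= log2(length(x)).
#' @return numeric vector of 2^level coefficients.
#' @export
haar_forward <- function(x, level) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L)
    stop("haar_forward() needs a power-of-2 signal length, got ", n)
  level <- as.integer(level)
  if (level < 1 || level > log2(n))
    stop("level must be between 1 and log2(length(x)) = ", log2(n))
  coefs <- numeric(2^level)
  coefs[1] <- mean(x)
  idx <- 2L
  for (j in 0:(level - 1L)) {
    parent <- block_means(x, 2^j)
    child <- block_means(x, 2^(j + 1L))
    d <- child[seq(1, length(child), by = 2)] - parent
    coefs[idx:(idx + 2^j - 1L)] <- d
    idx <- idx + 2^j
  }
  coefs
}

#' Derived step attributes from the inverse Haar transform
#'
#' Reconstructs from the 2^level coefficients of [haar_forward()] the
#' stepwise approximation of the original curve with 2^level steps of equal
#' width. Attribute j equals the mean of the signal over block j of
#' consecutive samples, in acquisition order; these step heights are the
#' derived attributes `w{level}coef0 ... w{level}coef{2^level-1}` used for
#' classification.
#'
#' @param coefs coefficient vector of length 2^level.
#' @param level decomposition level k.
#' @return object of class `wavelet_attributes`: list with `level` and the
#'   named attribute vector `coefs`.
#' @export
haar_inverse_attributes <- function(coefs, level) {
  level <- as.integer(level)
  if (length(coefs) != 2^level)
    stop("expected ", 2^level, " coefficients for level ", level,
         ", got ", length(coefs))
  m <- coefs[1]
  idx <- 2L
  for (j in 0:(level - 1L)) {
    d <- coefs[idx:(idx + 2^j - 1L)]
    left <- m + d
    right <- m - d          # parent mean is the average of the two halves
    m <- as.vector(rbind(left, right))
    idx <- idx + 2^j
  }
  names(m) <- paste0("w", level, "coef", seq_along(m) - 1L)
  structure(list(level = level, coefs = m), class = "wavelet_attributes")
}

#' @export
print.wavelet_attributes <- function(x, ...) {
  cat(sprintf("<wavelet_attributes> level %d: %d step attributes\n",
              x$level, length(x$coefs)))
  invisible(x)
}

#' Level-k wavelet step attributes of a curve
#'
#' Convenience chain truncate_to_pow2 -> haar_forward ->
#' haar_inverse_attributes.
#'
#' @param curve a [voltammogram()] or numeric vector (518 samples or a
#'   power of 2).
#' @param level decomposition level (default 5, giving 32 attributes).
#' @return a `wavelet_attributes` object.
#' @export
wavelet_attributes <- function(curve, level = 5) {
  x <- truncate_to_pow2(curve)
  haar_inverse_attributes(haar_forward(x, level), level)
}
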