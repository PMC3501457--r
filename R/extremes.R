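#' First-order FIR differentiator
#'
#' Discrete first difference `y[n] = x[n] - x[n-1]`, with a leading zero so
#' the output has the same length as the input.
#'
#' @param x numeric signal, length >= 2.
#' @return numeric vector, same length as `x`.
#' @export
differentiate <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("differentiate() needs a numeric signal of length >= 2")
  c(0, diff(x))
}

#' Signum-like normalization of a difference signal
#'
#' Maps inputs greater than or equal to zero to +0.5 and everything else to
#' -0.5. The zero-to-plus convention fixes the tie-breaking behaviour of
#' [find_extremes()] on flat runs.
#'
#' @param d numeric signal.
#' @return vector of +0.5 / -0.5, same length.
#' @export
sign_normalize <- function(d) {
  ifelse(d >= 0, 0.5, -0.5)
}

extreme_set <- function(position, potential, value, kind, n_samples) {
  structure(
    data.frame(position = as.integer(position), potential = potential,
               value = value, kind = kind, stringsAsFactors = FALSE),
    class = c("extreme_set", "data.frame"), n_samples = n_samples)
}

#' Locate local extremes of a voltammogram by discrete differentiation
#'
#' Applies the chain differentiate -> sign_normalize -> differentiate; the
#' nonzero entries of the final signal mark sign changes of the first
#' difference, i.e. local extremes of the input. Values are read off the
#' original signal at the marked indices. Curve endpoints are never
#' reported as extremes.
#'
#' Tie rule (flat runs): because zero differences normalize to +0.5, an
#' interior sample `e` is a maximum iff `x[e] >= x[e-1]` and `x[e] > x[e+1]`,
#' and a minimum iff `x[e] < x[e-1]` and `x[e] <= x[e+1]`.
#'
#' @param curve a [voltammogram()] or numeric current vector.
#' @param potentials optional potentials when `curve` is a bare vector.
#' @return an `extreme_set`: data frame with columns `position` (sample
#'   index), `potential`, `value` and `kind` (`"min"`/`"max"`).
#' @export
find_extremes <- function(curve, potentials = NULL) {
  if (inherits(curve, "voltammogram")) {
    x <- curve$currents
    potentials <- curve$potentials
  } else {
    x <- as.numeric(curve)
    if (is.null(potentials)) potentials <- seq_along(x)
  }
  n <- length(x)
  d <- differentiate(x)
  s <- sign_normalize(d)
  t2 <- differentiate(s)
  marks <- which(t2 != 0)
  pos <- marks - 1L            # the extreme sits one sample before the flip
  kind <- ifelse(t2[marks] < 0, "max", "min")
  keep <- pos > 1L & pos < n
  pos <- pos[keep]; kind <- kind[keep]
  extreme_set(pos, potentials[pos], x[pos], kind, n)
}

# absolute deviation of each extreme's value from the mean of its flanking
# extremes' values (curve implicitly flat beyond the ends: missing flank is
# ignored); used as a prominence score
extreme_prominence <- function(values) {
  n <- length(values)
  if (n == 0) return(numeric(0))
  if (n == 1) return(abs(values))
  left <- c(values[1], values[-n])
  right <- c(values[-1], values[n])
  abs(values - (left + right) / 2)
}

#' Merge local extremes that are closer than a minimum index distance
#'
#' Distances between neighbouring extremes are taken by differencing their
#' positions; for each pair closer than `min_distance`, the member whose
#' current deviates less from the mean of its flanking extremes is removed.
#' This is repeated until no pair violates the threshold; finally strict
#' min/max alternation is restored by dropping the weaker member of any
#' same-kind adjacent pair (the lower of two maxima, the higher of two
#' minima). The operation is idempotent.
#'
#' @param e an `extreme_set` from [find_extremes()].
#' @param min_distance minimum allowed index distance (>= 1); the default of
#'   5 samples corresponds to 10 mV at the 2 mV acquisition step.
#' @return a filtered `extreme_set`.
#' @export
merge_close_extremes <- function(e, min_distance = 5) {
  stopifnot(inherits(e, "extreme_set"), min_distance >= 1)
  n_samples <- attr(e, "n_samples")
  df <- as.data.frame(e)
  repeat {
    if (nrow(df) < 2) break
    gaps <- diff(df$position)
    bad <- which(gaps < min_distance)
    if (length(bad) == 0) break
    i <- bad[1]
    prom <- extreme_prominence(df$value)
    drop <- if (prom[i] <= prom[i + 1]) i else i + 1L
    df <- df[-drop, , drop = FALSE]
  }
  # restore alternation of kinds
  repeat {
    if (nrow(df) < 2) break
    same <- which(df$kind[-nrow(df)] == df$kind[-1])
    if (length(same) == 0) break
    i <- same[1]
    pair <- df[c(i, i + 1L), ]
    drop <- if (pair$kind[1] == "max") {
      if (pair$value[1] >= pair$value[2]) i + 1L else i
    } else {
      if (pair$value[1] <= pair$value[2]) i + 1L else i
    }
    df <- df[-drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  extreme_set(df$position, df$potential, df$value, df$kind, n_samples)
}

#' Default potential windows for peak naming
#'
#' Acquisition-order potential intervals (volts) in which each named peak of
#' the Brdicka curve is sought. The minima windows follow the catalytic-peak
#' ranges reported for the Brdicka reaction (RS2Co near -1.2 to -1.35 V,
#' Cat1 and Cat2 more negative); the maxima windows bracket the ridges
#' between them and the last maximum Max3 before the hydrogen-evolution
#' wall. All windows are configurable.
#'
#' @return named list of `list(kind, lo, hi)` window definitions.
#' @export
default_peak_windows <- function() {
  list(
    co1   = list(kind = "min", lo = -0.95, hi = -0.70),
    rs2co = list(kind = "min", lo = -1.35, hi = -1.10),
    cat1  = list(kind = "min", lo = -1.48, hi = -1.30),
    cat2  = list(kind = "min", lo = -1.62, hi = -1.45),
    max1  = list(kind = "max", lo = -1.39, hi = -1.22),
    max2  = list(kind = "max", lo = -1.49, hi = -1.39),
    max3  = list(kind = "max", lo = -1.70, hi = -1.49)
  )
}

check_windows <- function(windows) {
  nm <- names(windows)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!all(c("kind", "lo", "hi") %in% names(w)) || w$lo >= w$hi)
      stop("malformed peak window: ", nm[i])
    for (j in seq_along(windows)) {
      if (i == j) next
      v <- windows[[j]]
      if (identical(w$kind, v$kind) && w$lo <= v$lo && w$hi >= v$hi)
        stop("configuration error: window ", nm[i],
             " fully contains same-kind window ", nm[j])
    }
  }
  invisible(windows)
}

#' Assign peak names to merged extremes
#'
#' Each named peak is the unassigned extreme of the required kind inside its
#' potential window with the largest prominence (absolute deviation from the
#' mean of its flanking extremes). Names are assigned in order of
#' specificity (cat2, cat1, rs2co, co1, max3, max2, max1) and an extreme can
#' carry at most one name; unmatched names are left empty.
#'
#' @param e a merged `extreme_set`.
#' @param windows window definitions as from [default_peak_windows()].
#' @return object of class `named_peaks`: a named list whose elements are
#'   either `NULL` or `list(position, potential, value)`.
#' @export
name_peaks <- function(e, windows = default_peak_windows()) {
  stopifnot(inherits(e, "extreme_set"))
  check_windows(windows)
  order_names <- intersect(
    c("cat2", "cat1", "rs2co", "co1", "max3", "max2", "max1"),
    names(windows))
  order_names <- c(order_names, setdiff(names(windows), order_names))
  prom <- extreme_prominence(e$value)
  used <- rep(FALSE, nrow(e))
  out <- stats::setNames(vector("list", length(windows)), names(windows))
  for (nm in order_names) {
    w <- windows[[nm]]
    cand <- which(!used & e$kind == w$kind &
                    e$potential > w$lo & e$potential <= w$hi)
    if (length(cand) == 0) next
    pick <- cand[which.max(prom[cand])]
    used[pick] <- TRUE
    out[[nm]] <- list(position = e$position[pick],
                      potential = e$potential[pick],
                      value = e$value[pick])
  }
  structure(out, class = "named_peaks")
}

#' @export
print.named_peaks <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]])) cat(sprintf("  %-6s -\n", nm))
    else cat(sprintf("  %-6s %8.4f V  %10.5f\n", nm,
                     x[[nm]]$potential, x[[nm]]$value))
  }
  invisible(x)
}

#' Flag outlier replicates within one (tissue, subject) group
#'
#' Computes each curve's root-mean-square distance to the pointwise median
#' curve of the group and flags curves whose distance exceeds the group
#' median distance times `factor`. An explicit manual flag list overrides
#' the automatic rule.
#'
#' @param group list of [voltammogram()]s from one (tissue, subject) cell,
#'   at least 3 for automatic flagging.
#' @param factor multiplier on the median distance (default 5).
#' @param manual optional character vector of replicate ids to flag
#'   unconditionally (overrides the distance rule entirely).
#' @return logical vector, one flag per curve in `group`.
#' @export
flag_outlier_replicates <- function(group, factor = 5, manual = NULL) {
  stopifnot(is.list(group), length(group) >= 1)
  reps <- vapply(group, function(cv) cv$replicate, character(1))
  if (!is.null(manual)) return(reps %in% as.character(manual))
  if (length(group) < 3) {
    warning("fewer than 3 replicates: cannot flag automatically")
    return(rep(FALSE, length(group)))
  }
  mat <- vapply(group, function(cv) cv$currents,
                numeric(length(group[[1]]$currents)))
  med <- apply(mat, 1, stats::median)
  dist <- sqrt(colMeans((mat - med)^2))
  dist > factor * stats::median(dist)
}

#' Remove outlier replicates from a dataset
#'
#' Applies [flag_outlier_replicates()] to every (tissue, subject) group and
#' drops the flagged curves. Manual flags, given as a data frame with
#' columns `tissue`, `subject`, `replicate`, override the automatic rule in
#' the groups they mention.
#'
#' @param dataset a [brdicka_dataset()].
#' @param factor distance multiplier passed on.
#' @param manual_flags optional data frame of curves to drop; groups it
#'   mentions are cleaned by the list alone.
#' @param auto apply the automatic distance rule to groups not covered by
#'   `manual_flags` (default `TRUE`). With `auto = FALSE` the cleaning is
#'   purely manual, mirroring curation by visual inspection.
#' @return list with elements `dataset` (cleaned), `flagged` (data frame of
#'   removed curve labels) and `report` (named counts: before, flagged,
#'   after).
#' @export
clean_dataset <- function(dataset, factor = 5, manual_flags = NULL,
                          auto = TRUE) {
  stopifnot(inherits(dataset, "brdicka_dataset"))
  lab <- dataset_labels(dataset)
  grp <- paste(lab$tissue, lab$subject, sep = "/")
  drop <- logical(nrow(lab))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    man <- NULL
    if (!is.null(manual_flags)) {
      sel <- manual_flags$tissue == lab$tissue[idx[1]] &
        manual_flags$subject == lab$subject[idx[1]]
      if (any(sel)) man <- manual_flags$replicate[sel]
    }
    if (!is.null(man)) {
      drop[idx] <- lab$replicate[idx] %in% as.character(man)
    } else if (auto) {
      drop[idx] <- flag_outlier_replicates(dataset$curves[idx],
                                           factor = factor)
    }
  }
  cleaned <- brdicka_dataset(dataset$curves[!drop],
                             provenance = dataset$provenance)
  list(dataset = cleaned,
       flagged = lab[drop, , drop = FALSE],
       report = c(before = nrow(lab), flagged = sum(drop),
                  after = nrow(lab) - sum(drop)))
}
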