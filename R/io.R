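#' Construct a voltammogram
#'
#' A voltammogram is one labelled differential-pulse voltammetry curve:
#' equidistant potentials in acquisition order (from -0.7 V toward the most
#' negative potential, hence strictly decreasing) and the measured currents.
#' Currents are stored so that the catalytic peaks (RS2Co, Cat1, Cat2) are
#' local minima; plotted voltammograms in the electrochemical literature
#' mirror the current axis, which makes them look like maxima.
#'
#' @param potentials numeric vector of potentials in volts, strictly
#'   decreasing and equidistant (tolerance 1e-9 V).
#' @param currents numeric vector of currents (arbitrary units), same length.
#' @param tissue,subject,replicate curve labels.
#' @return an object of class `voltammogram`.
#' @export
voltammogram <- function(potentials, currents, tissue, subject, replicate) {
  potentials <- as.numeric(potentials)
  currents <- as.numeric(currents)
  if (length(potentials) != length(currents))
    stop("potentials and currents must have the same length")
  if (length(potentials) < 2) stop("a voltammogram needs at least 2 samples")
  st <- diff(potentials)
  if (any(st >= 0)) stop("potentials must be strictly decreasing (acquisition order)")
  if (max(st) - min(st) > 1e-9)
    stop("potentials must be equidistant (tolerance 1e-9 V)")
  structure(
    list(potentials = potentials, currents = currents,
         tissue = as.character(tissue), subject = as.character(subject),
         replicate = as.character(replicate)),
    class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("<voltammogram> %s / subject %s / replicate %s: %d samples in (%.3f, %.3f) V\n",
              x$tissue, x$subject, x$replicate, length(x$potentials),
              min(x$potentials), max(x$potentials)))
  invisible(x)
}

curve_key <- function(cv) paste(cv$tissue, cv$subject, cv$replicate, sep = "/")

#' Construct a curve dataset
#'
#' @param curves list of [voltammogram()] objects with unique
#'   (tissue, subject, replicate) keys.
#' @param provenance free-text provenance note.
#' @return object of class `brdicka_dataset`.
#' @export
brdicka_dataset <- function(curves, provenance = "") {
  stopifnot(is.list(curves))
  if (length(curves) > 0) {
    ok <- vapply(curves, inherits, logical(1), "voltammogram")
    if (!all(ok)) stop("all elements of `curves` must be voltammograms")
    keys <- vapply(curves, curve_key, character(1))
    if (anyDuplicated(keys))
      stop("duplicate (tissue, subject, replicate) keys: ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  structure(list(curves = curves, provenance = provenance),
            class = "brdicka_dataset")
}

#' @export
print.brdicka_dataset <- function(x, ...) {
  tiss <- unique(vapply(x$curves, function(cv) cv$tissue, character(1)))
  cat(sprintf("<brdicka_dataset> %d curves, %d tissues\n",
              length(x$curves), length(tiss)))
  invisible(x)
}

#' Number of curves in a dataset
#' @param dataset a `brdicka_dataset`.
#' @return integer count.
#' @export
n_curves <- function(dataset) length(dataset$curves)

dataset_labels <- function(dataset) {
  data.frame(
    tissue = vapply(dataset$curves, function(cv) cv$tissue, character(1)),
    subject = vapply(dataset$curves, function(cv) cv$subject, character(1)),
    replicate = vapply(dataset$curves, function(cv) cv$replicate, character(1)),
    stringsAsFactors = FALSE)
}

#' Write a curve dataset to a text file
#'
#' Two dialects are supported. `tidy-csv` has one row per sample with columns
#' `tissue, subject, replicate, potential_V, current`. `wide-tsv` has one
#' curve per row: the label columns followed by one column per potential,
#' named by the potential value. Numbers are written with 15 significant
#' digits so that a write/read round trip preserves currents to better than
#' 1e-12 relative.
#'
#' @param dataset a [brdicka_dataset()].
#' @param path output file path.
#' @param dialect `"tidy-csv"` or `"wide-tsv"`.
#' @return `path`, invisibly.
#' @export
write_curves <- function(dataset, path, dialect = c("tidy-csv", "wide-tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "brdicka_dataset"))
  fmt <- function(x) sprintf("%.15g", x)
  if (dialect == "tidy-csv") {
    lines <- "tissue,subject,replicate,potential_V,current"
    for (cv in dataset$curves) {
      lines <- c(lines, paste(cv$tissue, cv$subject, cv$replicate,
                              fmt(cv$potentials), fmt(cv$currents), sep = ","))
    }
    writeLines(lines, path, useBytes = TRUE)
  } else {
    if (length(dataset$curves) == 0) {
      writeLines("tissue\tsubject\treplicate", path, useBytes = TRUE)
      return(invisible(path))
    }
    pots <- dataset$curves[[1]]$potentials
    for (cv in dataset$curves)
      if (length(cv$potentials) != length(pots) ||
          max(abs(cv$potentials - pots)) > 1e-9)
        stop("wide-tsv requires all curves on a common potential grid")
    header <- paste(c("tissue", "subject", "replicate", fmt(pots)),
                    collapse = "\t")
    rows <- vapply(dataset$curves, function(cv)
      paste(c(cv$tissue, cv$subject, cv$replicate, fmt(cv$currents)),
            collapse = "\t"), character(1))
    writeLines(c(header, rows), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a curve dataset from a text file
#'
#' Inverse of [write_curves()]. Validates per-curve sample counts,
#' equidistance of potentials (tolerance 1e-9 V) and uniqueness of curve
#' keys.
#'
#' @param path input file path.
#' @param dialect `"tidy-csv"` or `"wide-tsv"`.
#' @param n_points if not `NULL`, required number of samples per curve;
#'   curves of any other length raise a validation error.
#' @return a [brdicka_dataset()].
#' @export
read_curves <- function(path, dialect = c("tidy-csv", "wide-tsv"),
                        n_points = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tidy-csv") {
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) == 0) stop("empty file: ", path)
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    expect <- c("tissue", "subject", "replicate", "potential_V", "current")
    if (!identical(header, expect))
      stop("tidy-csv header must be: ", paste(expect, collapse = ","))
    if (length(lines) == 1)
      return(brdicka_dataset(list(), provenance = path))
    parts <- strsplit(lines[-1], ",", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 5))
      stop("parse error at line ", which(nf != 5)[1] + 1L,
           ": expected 5 fields, got ", nf[nf != 5][1])
    m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
    pot <- suppressWarnings(as.numeric(m[, 4]))
    cur <- suppressWarnings(as.numeric(m[, 5]))
    bad <- which(is.na(pot) | is.na(cur))
    if (length(bad))
      stop("parse error at line ", bad[1] + 1L, ": non-numeric sample")
    key <- paste(m[, 1], m[, 2], m[, 3], sep = "/")
    idx <- split(seq_along(key), factor(key, levels = unique(key)))
    curves <- lapply(idx, function(i)
      voltammogram(pot[i], cur[i], m[i[1], 1], m[i[1], 2], m[i[1], 3]))
    names(curves) <- NULL
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) == 0) stop("empty file: ", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(header) < 3 ||
        !identical(header[1:3], c("tissue", "subject", "replicate")))
      stop("wide-tsv header must start with tissue, subject, replicate")
    pots <- as.numeric(header[-(1:3)])
    if (anyNA(pots) && length(header) > 3)
      stop("wide-tsv header potentials must be numeric")
    curves <- vector("list", length(lines) - 1L)
    for (i in seq_along(curves)) {
      f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
      if (length(f) != length(header))
        stop("parse error at line ", i + 1L, ": expected ",
             length(header), " fields, got ", length(f))
      cur <- suppressWarnings(as.numeric(f[-(1:3)]))
      if (anyNA(cur))
        stop("parse error at line ", i + 1L, ": non-numeric sample")
      curves[[i]] <- voltammogram(pots, cur, f[1], f[2], f[3])
    }
  }
  if (!is.null(n_points)) {
    len <- vapply(curves, function(cv) length(cv$currents), integer(1))
    if (any(len != n_points))
      stop("validation error: curve ", which(len != n_points)[1],
           " has ", len[len != n_points][1], " samples, expected ", n_points)
  }
  brdicka_dataset(curves, provenance = path)
}
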