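#' RadViz anchor layout
#'
#' Places one circular anchor per attribute. By default anchors are equally
#' spaced counterclockwise on the unit circle starting at angle 0, in
#' attribute order.
#'
#' @param attributes character vector of attribute names.
#' @param angles optional anchor angles in radians (distinct, one per
#'   attribute).
#' @return object of class `radviz_layout`.
#' @export
radviz_layout <- function(attributes, angles = NULL) {
  n <- length(attributes)
  stopifnot(n >= 1)
  if (is.null(angles)) angles <- 2 * pi * (seq_len(n) - 1) / n
  if (length(angles) != n) stop("need one angle per attribute")
  if (anyDuplicated(angles)) stop("anchor angles must be distinct")
  structure(list(attributes = attributes, angles = angles),
            class = "radviz_layout")
}

#' RadViz projection of multidimensional points into the plane
#'
#' Hooke-law (spring) formulation: each row y is mapped to the weighted
#' centroid of the anchor positions, `u = sum_j y'_j (cos a_j, sin a_j) /
#' sum_j y'_j`. With `normalize = TRUE` every attribute is min-max scaled
#' to \[0, 1\] over the dataset first (a constant attribute scales to 0).
#' Rows whose weights sum to zero map to the origin. Projected points
#' always lie inside the convex hull of the anchors.
#'
#' @param points numeric matrix or data frame, one row per observation;
#'   column count must match the layout.
#' @param layout a [radviz_layout()].
#' @param normalize min-max scale attributes first (default `TRUE`).
#' @return matrix with columns `x`, `y`, one row per input row.
#' @export
radviz_project <- function(points, layout, normalize = TRUE) {
  stopifnot(inherits(layout, "radviz_layout"))
  m <- as.matrix(points)
  if (ncol(m) != length(layout$attributes))
    stop("dimension mismatch: ", ncol(m), " columns vs ",
         length(layout$attributes), " anchors")
  if (normalize) {
    rng <- apply(m, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- Inf                 # constant attribute -> weight 0
    m <- sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
  }
  w <- rowSums(m)
  ux <- as.vector(m %*% cos(layout$angles))
  uy <- as.vector(m %*% sin(layout$angles))
  zero <- w == 0
  w[zero] <- 1
  out <- cbind(x = ux / w, y = uy / w)
  out[zero, ] <- 0
  out
}

#' RadViz projection of selected wavelet attributes
#'
#' Projects each curve of a `wavelet32` feature table onto the plane using
#' four anchors for the attributes covering the Cat2-to-Max3 stretch
#' (w5coef24 ... w5coef27 by default), carrying the tissue labels through
#' for plotting.
#'
#' @param table a `feature_table` in `wavelet32` mode.
#' @param attrs attribute names to project (default w5coef24..w5coef27).
#' @param normalize passed to [radviz_project()].
#' @return data frame with columns `x`, `y`, `tissue`, `subject`,
#'   `replicate`.
#' @export
project_wavelet_subset <- function(table,
                                   attrs = paste0("w5coef", 24:27),
                                   normalize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(attrs, colnames(table))
  if (length(miss))
    stop("missing attributes: ", paste(miss, collapse = ", "))
  uv <- radviz_project(as.data.frame(table)[attrs],
                       radviz_layout(attrs), normalize)
  data.frame(x = uv[, "x"], y = uv[, "y"],
             tissue = table$tissue, subject = table$subject,
             replicate = table$replicate, stringsAsFactors = FALSE)
}
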