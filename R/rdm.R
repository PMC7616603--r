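#' Construct a representational dissimilarity matrix (RDM)
#'
#' An RDM is a labelled, symmetric, zero-diagonal matrix of pairwise
#' dissimilarities between items (here, trials), tagged with the metric that
#' produced it. Entry ranges are metric-specific and enforced:
#' Euclidean-on-binary entries lie in \{0, 1\}, cosine distances in
#' \[0, 2\] (\[0, 1\] for non-negative vectors), correlation distances in
#' \[0, 2\].
#'
#' @param matrix square numeric matrix of dissimilarities.
#' @param labels item identifiers, one per row/column.
#' @param metric one of `"euclidean"`, `"cosine"`, `"correlation"`.
#' @return an object of class `rdm`.
#' @export
rdm <- function(matrix, labels, metric = c("euclidean", "cosine",
                                           "correlation")) {
  metric <- match.arg(metric)
  m <- as.matrix(matrix)
  labels <- as.character(labels)
  x <- structure(list(labels = labels, matrix = m, metric = metric),
                 class = "rdm")
  validate_rdm(x)
}

#' @rdname rdm
#' @param x an `rdm` to validate.
#' @export
validate_rdm <- function(x) {
  stopifnot(inherits(x, "rdm"))
  m <- x$matrix
  if (nrow(m) != ncol(m) || nrow(m) < 2L) {
    stop_scenersa("RDM must be square with at least 2 items",
                  class = "scenersa_rdm_error")
  }
  if (length(x$labels) != nrow(m)) {
    stop_scenersa("RDM has ", nrow(m), " items but ", length(x$labels),
                  " labels", class = "scenersa_rdm_error")
  }
  if (any(diag(m) != 0)) {
    stop_scenersa("RDM diagonal must be exactly 0",
                  class = "scenersa_rdm_error")
  }
  if (max(abs(m - t(m))) > 1e-12) {
    stop_scenersa("RDM not symmetric (max asymmetry ",
                  format(max(abs(m - t(m)))), ")",
                  class = "scenersa_rdm_error")
  }
  rng <- switch(x$metric,
                euclidean = c(0, Inf),
                cosine = c(0, 2 + 1e-12),
                correlation = c(0, 2 + 1e-12))
  if (min(m) < -1e-12 || max(m) > rng[2L]) {
    stop_scenersa("RDM entries outside the valid range for metric '",
                  x$metric, "'", class = "scenersa_rdm_error")
  }
  invisible(x)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d x %d, metric %s\n", nrow(x$matrix), nrow(x$matrix),
              x$metric))
  tri <- lower_triangle(x)
  cat(sprintf("  off-diagonal range [%.4g, %.4g], mean %.4g\n",
              min(tri), max(tri), mean(tri)))
  invisible(x)
}

#' Strictly-lower-triangle vectorisation of an RDM
#'
#' The canonical vectorisation used for model-neural comparison: entries
#' below the diagonal in column-major order, diagonal excluded.
#'
#' @param x an `rdm` or square matrix.
#' @return numeric vector of length n(n-1)/2.
#' @export
lower_triangle <- function(x) {
  m <- if (inherits(x, "rdm")) x$matrix else x
  m[lower.tri(m)]
}

#' Subset an RDM to a label set
#'
#' @param x an `rdm`.
#' @param labels labels to retain, in the requested order; must all be
#'   present in `x$labels`.
#' @return the restricted `rdm`.
#' @export
subset_rdm <- function(x, labels) {
  labels <- as.character(labels)
  pos <- match(labels, x$labels)
  if (anyNA(pos)) {
    stop_scenersa("unknown label(s): ",
                  paste(labels[is.na(pos)], collapse = ", "),
                  class = "scenersa_rdm_error")
  }
  rdm(x$matrix[pos, pos, drop = FALSE], labels, x$metric)
}

#' Cosine distance between two non-negative feature vectors
#'
#' `1 - u.v / (||u|| ||v||)`; lies in \[0, 1\] for non-negative inputs.
#' Used for semantic model RDMs over property-norm feature vectors.
#'
#' @param u,v numeric vectors of equal length, each with at least one
#'   positive entry.
#' @return the cosine distance.
#' @export
cosine_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_scenersa("cosine distance undefined for a zero vector",
                  class = "scenersa_distance_error")
  }
  d <- 1 - sum(u * v) / (nu * nv)
  # clamp floating-point leakage just outside [0, 2]
  min(max(d, 0), 2)
}

#' Correlation distance between two patterns
#'
#' `1 - Pearson(p, q)`, in \[0, 2\]. The pattern vectors are channel
#' amplitudes at one timepoint; a constant pattern has no defined
#' correlation and raises an error rather than propagating NaN.
#'
#' @param p,q numeric vectors of equal length >= 3, non-constant.
#' @return the correlation distance.
#' @export
correlation_distance <- function(p, q) {
  stopifnot(length(p) == length(q), length(p) >= 3L)
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    stop_scenersa("correlation distance undefined for a constant pattern",
                  class = "scenersa_distance_error")
  }
  d <- 1 - stats::cor(p, q)
  min(max(d, 0), 2)
}
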