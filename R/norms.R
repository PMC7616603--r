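#' Construct a concept-by-feature property-norm matrix
#'
#' Property norms describe each object concept by the semantic features
#' people list for it (a zebra "has stripes", "eats grass"). Values are
#' non-negative (typically binary presence or production frequencies);
#' a concept with no positive feature is invalid. Concept names are
#' case-normalised to lower case and must be unique after normalisation.
#'
#' @param values non-negative numeric matrix, concepts in rows, features in
#'   columns.
#' @param concepts,features row and column names; taken from `dimnames(values)`
#'   when omitted.
#' @return an object of class `feature_norms`.
#' @export
feature_norms <- function(values, concepts = rownames(values),
                          features = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(concepts) || is.null(features)) {
    stop_scenersa("feature_norms needs concept and feature names",
                  class = "scenersa_norms_error")
  }
  concepts <- tolower(trimws(as.character(concepts)))
  features <- as.character(features)
  if (anyDuplicated(concepts)) {
    dup <- concepts[duplicated(concepts)][1L]
    stop_scenersa("duplicate concept after case normalisation: '", dup, "'",
                  class = "scenersa_norms_error")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_scenersa("norm values must be finite numbers",
                  class = "scenersa_norms_error")
  }
  if (any(values < 0)) {
    stop_scenersa("negative norm value for concept '",
                  concepts[which(values < 0, arr.ind = TRUE)[1L, 1L]], "'",
                  class = "scenersa_norms_error")
  }
  zero <- rowSums(values) == 0
  if (any(zero)) {
    stop_scenersa("concept with no features: '", concepts[which(zero)[1L]],
                  "'", class = "scenersa_norms_error")
  }
  dimnames(values) <- list(concepts, features)
  structure(list(values = values), class = "feature_norms")
}

#' @export
print.feature_norms <- function(x, ...) {
  cat(sprintf("<feature_norms> %d concepts x %d features, %.1f%% nonzero\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$values > 0)))
  invisible(x)
}

#' Concept names of a feature_norms object
#' @param norms a `feature_norms`.
#' @return character vector of (lower-cased) concept names.
#' @export
concepts <- function(norms) rownames(norms$values)

#' Feature vector for one concept
#' @param norms a `feature_norms`.
#' @param concept concept name (case-insensitive).
#' @return numeric feature vector.
#' @export
feature_vector <- function(norms, concept) {
  key <- tolower(trimws(concept))
  if (!key %in% rownames(norms$values)) {
    stop_scenersa("concept not in norms: '", concept, "'",
                  class = "scenersa_norms_error")
  }
  norms$values[key, ]
}

#' Read property norms from TSV
#'
#' Accepts either long form — three columns `concept`, `feature`, `value` —
#' or a wide matrix whose header row holds feature names and whose first
#' column holds concept names. The form is auto-detected from the header.
#' Duplicate (concept, feature) pairs in long form are an error, as are
#' negative values and concepts with no positive feature.
#'
#' @param path TSV file path.
#' @return a `feature_norms`.
#' @export
read_feature_norms <- function(path) {
  if (!file.exists(path)) {
    stop_scenersa("no such file: ", path, class = "scenersa_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  long_form <- length(header) == 3L &&
    identical(tolower(header[1:2]), c("concept", "feature"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "")
  if (long_form) {
    tab[[1L]] <- tolower(trimws(tab[[1L]]))
    key <- paste(tab[[1L]], tab[[2L]], sep = "\r")
    if (anyDuplicated(key)) {
      d <- tab[duplicated(key), , drop = FALSE][1L, ]
      stop_scenersa("duplicate (concept, feature) pair: ('", d[[1L]], "', '",
                    d[[2L]], "')", class = "scenersa_norms_error")
    }
    cns <- sort(unique(tab[[1L]]))
    fts <- sort(unique(tab[[2L]]))
    m <- matrix(0, length(cns), length(fts), dimnames = list(cns, fts))
    m[cbind(match(tab[[1L]], cns), match(tab[[2L]], fts))] <-
      as.numeric(tab[[3L]])
    feature_norms(m)
  } else {
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- tab[[1L]]
    feature_norms(m)
  }
}

#' Write property norms as wide TSV
#' @param norms a `feature_norms`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_norms <- function(norms, path) {
  out <- data.frame(concept = rownames(norms$values),
                    norms$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
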