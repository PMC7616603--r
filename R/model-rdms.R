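#' Binary congruency model RDM
#'
#' Codes each kept trial 1 (congruent) or 0 (incongruent) and takes the
#' Euclidean distance between the scalar codes, so same-condition pairs get
#' dissimilarity 0 and cross-condition pairs 1. With the full counterbalanced
#' design (76 trials per condition) this is a 152 x 152 matrix. The model is
#' participant-specific because the condition assignment of each scene
#' differs across counterbalancing groups.
#'
#' @param trials a `trial_table`; only `keep = TRUE` rows enter the model.
#' @return an `rdm` labelled by `trial_id`, metric `"euclidean"`.
#' @export
build_congruency_rdm <- function(trials) {
  validate_trial_table(trials)
  tab <- trials[trials$keep, , drop = FALSE]
  if (nrow(tab) < 2L) {
    stop_scenersa("need at least 2 kept trials to build a model RDM",
                  class = "scenersa_rdm_error")
  }
  code <- as.numeric(tab$condition == "congruent")
  if (all(code == code[1L])) {
    warning("only one condition present: congruency RDM is all zero",
            call. = FALSE)
  }
  m <- abs(outer(code, code, "-"))
  rdm(m, labels = tab$trial_id, metric = "euclidean")
}

#' Match trial object labels to property-norm concepts
#'
#' Deterministic two-step matching: (1) exact equality after lower-casing
#' and trimming whitespace; else (2) lookup in a user-supplied alias table
#' mapping object labels to concept names; else unmatched. No fuzzy
#' matching is attempted, so exclusions are fully auditable. Every alias
#' must point at a concept present in the norms.
#'
#' @param trials a `trial_table`.
#' @param norms a `feature_norms`.
#' @param aliases named character vector (or NULL): names are object labels,
#'   values are concept names; see [read_alias_table()].
#' @return a data.frame with columns trial_id, object_label,
#'   matched_concept (NA when unmatched) and matched.
#' @export
match_concepts <- function(trials, norms, aliases = NULL) {
  validate_trial_table(trials)
  pool <- concepts(norms)
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(names(aliases) == "")) {
      stop_scenersa("alias table must map object labels to concept names",
                    class = "scenersa_config_error")
    }
    tgt <- tolower(trimws(aliases))
    bad <- !(tgt %in% pool)
    if (any(bad)) {
      stop_scenersa("alias target(s) absent from the norms: ",
                    paste(unique(tgt[bad]), collapse = ", "),
                    class = "scenersa_config_error")
    }
    names(aliases) <- tolower(trimws(names(aliases)))
    aliases[] <- tgt
  }
  key <- tolower(trimws(trials$object_label))
  matched_concept <- ifelse(key %in% pool, key, NA_character_)
  if (!is.null(aliases)) {
    needs <- is.na(matched_concept) & key %in% names(aliases)
    matched_concept[needs] <- unname(aliases[key[needs]])
  }
  out <- data.frame(
    trial_id = trials$trial_id,
    object_label = trials$object_label,
    matched_concept = matched_concept,
    matched = !is.na(matched_concept),
    stringsAsFactors = FALSE
  )
  n_un <- sum(!out$matched)
  if (n_un > 0) {
    message("no norm concept for ", n_un, " of ", nrow(out),
            " trials; they are excluded from semantic analysis")
  }
  out
}

#' Read an object-label to concept alias table
#' @param path TSV with two columns, `object_label` and `concept`.
#' @return named character vector usable as `aliases` in [match_concepts()].
#' @export
read_alias_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Semantic model RDM for one condition
#'
#' Builds the cosine-distance matrix over the property-norm feature vectors
#' of all kept, concept-matched trials in the requested condition. Labels
#' carry `trial_id`s so the neural RDM series can be subset to exactly the
#' same trials in the same order. Trials without a norm match are excluded
#' here but not from the congruency analysis.
#'
#' @param trials a `trial_table`.
#' @param matches result of [match_concepts()] for the same trials.
#' @param norms a `feature_norms`.
#' @param condition `"congruent"` or `"incongruent"`.
#' @param binarise if TRUE, feature values are thresholded at > 0 before
#'   computing distances (default FALSE: values used as given).
#' @return an `rdm` with metric `"cosine"`.
#' @export
build_semantic_rdm <- function(trials, matches, norms,
                               condition = c("congruent", "incongruent"),
                               binarise = FALSE) {
  condition <- match.arg(condition)
  validate_trial_table(trials)
  info <- merge(as.data.frame(trials), matches[, c("trial_id",
                                                   "matched_concept",
                                                   "matched")],
                by = "trial_id", sort = FALSE)
  use <- info$keep & info$matched & info$condition == condition
  info <- info[use, , drop = FALSE]
  info <- info[order(info$trial_id), , drop = FALSE]
  if (nrow(info) < 2L) {
    stop_scenersa("fewer than 2 kept, matched trials in condition '",
                  condition, "'", class = "scenersa_rdm_error")
  }
  vecs <- norms$values[info$matched_concept, , drop = FALSE]
  if (binarise) vecs <- (vecs > 0) * 1
  n <- nrow(vecs)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- cosine_distance(vecs[i, ], vecs[j, ])
    }
  }
  rdm(m, labels = info$trial_id, metric = "cosine")
}

#' Export an RDM as a TSV matrix
#' @param x an `rdm`.
#' @param path output path; header row and first column hold the labels.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(x, path) {
  out <- data.frame(label = x$labels, x$matrix, check.names = FALSE)
  colnames(out) <- c("label", x$labels)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
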