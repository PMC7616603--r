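#' Per-subject preprocessing and neural RDM computation
#'
#' The shared front end of the analyses: load (when given a file path),
#' flag noisy trials, baseline-correct, then compute the per-timepoint
#' neural RDM series over kept trials. Stage failures are re-raised naming
#' the subject and stage.
#'
#' @param subject an `epoch_set` or a path to an HDF5 epoch container.
#' @param baseline_window closed baseline window in ms (NULL to skip).
#' @param ptp_threshold_uv,zvar_threshold thresholds for
#'   [reject_noisy_trials()] (NULL skips rejection).
#' @return list with `epochs` (preprocessed) and `series` (`rdm_series`).
#' @export
prepare_subject <- function(subject, baseline_window = c(-200, 0),
                            ptp_threshold_uv = 200, zvar_threshold = 4) {
  stage <- "load"
  tryCatch({
    epochs <- if (is.character(subject)) read_epochs(subject) else subject
    sid <- epochs$subject_id
    if (!is.null(ptp_threshold_uv)) {
      stage <- "noisy-trial rejection"
      epochs <- reject_noisy_trials(epochs, ptp_threshold_uv, zvar_threshold)
    }
    if (!is.null(baseline_window)) {
      stage <- "baseline correction"
      epochs <- baseline_correct(epochs, baseline_window[1L],
                                 baseline_window[2L])
    }
    stage <- "neural RDM computation"
    list(epochs = epochs, series = neural_rdm_series(epochs))
  }, scenersa_error = function(e) {
    sid <- if (is.character(subject)) subject else subject$subject_id
    stop_scenersa("subject ", sid, ", stage '", stage, "': ",
                  conditionMessage(e), class = class(e)[1L])
  })
}

pipeline_provenance <- function(params, subjects, extra = list()) {
  input_hashes <- vapply(subjects, function(s) {
    if (is.character(s)) unname(tools::md5sum(s)) else epochs_content_hash(s)
  }, character(1L))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA), tmp)
  c(list(package_version = as.character(utils::packageVersion("scenersa")),
         config_hash = unname(tools::md5sum(tmp)),
         input_hashes = as.list(input_hashes)),
    extra)
}

#' Group congruency-model RSA analysis
#'
#' The end-to-end congruency analysis: per subject, preprocess, compute the
#' neural RDM series, build the participant-specific binary congruency
#' model RDM from that subject's own trial table, and Spearman-correlate
#' model and neural RDMs at every timepoint; then test the per-subject fit
#' time series against zero with the sign-flip cluster-mass permutation
#' test.
#'
#' @param subjects list of `epoch_set` objects and/or container paths
#'   (>= 3).
#' @param alpha cluster-forming alpha (default 0.01).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed for the permutation RNG.
#' @param tail `"two"` or `"pos"` cluster-forming tail.
#' @param baseline_window,ptp_threshold_uv,zvar_threshold see
#'   [prepare_subject()].
#' @param out_dir optional directory; when set, writes
#'   `rsa_timeseries.tsv` and `clusters_congruency.json` with full
#'   provenance.
#' @return an `rsa_cluster_test`, with the per-subject `rsa_timeseries`
#'   list attached as attribute `"fits"`.
#' @export
run_congruency_analysis <- function(subjects, alpha = 0.01, n_perm = 10000,
                                    seed, tail = "two",
                                    baseline_window = c(-200, 0),
                                    ptp_threshold_uv = 200,
                                    zvar_threshold = 4, out_dir = NULL) {
  if (length(subjects) < 3L) {
    stop_scenersa("need >= 3 subjects", class = "scenersa_inference_error")
  }
  fits <- lapply(subjects, function(s) {
    prep <- prepare_subject(s, baseline_window, ptp_threshold_uv,
                            zvar_threshold)
    model <- build_congruency_rdm(prep$epochs$trials)
    rsa_timeseries(prep$series, model, subject_id = prep$epochs$subject_id)
  })
  rhos <- stack_rsa(fits)
  fit <- signflip_cluster_test(rhos, alpha = alpha, n_perm = n_perm,
                               seed = seed, tail = tail)
  attr(fit, "fits") <- fits
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rsa_tsv(fits, file.path(out_dir, "rsa_timeseries.tsv"),
                  model = "congruency")
    params <- list(analysis = "congruency", alpha = alpha, n_perm = n_perm,
                   seed = seed, tail = tail,
                   baseline_window = baseline_window,
                   ptp_threshold_uv = ptp_threshold_uv,
                   zvar_threshold = zvar_threshold)
    write_cluster_report(fit, file.path(out_dir, "clusters_congruency.json"),
                         model = "congruency", condition = "all",
                         extra = pipeline_provenance(params, subjects))
  }
  fit
}

#' Group semantic-model RSA analysis
#'
#' Per subject and condition: match the subject's object labels to the
#' property norms, build the cosine semantic model RDM over matched kept
#' trials of that condition, subset the neural RDM series to the same
#' trials, and compute the Spearman fit time series. Group level: a
#' one-sample sign-flip cluster test per condition plus a paired
#' cluster test on the per-subject condition difference. Subjects with
#' fewer than 2 usable trials in either condition are excluded with a
#' warning; exclusion counts are reported.
#'
#' @inheritParams run_congruency_analysis
#' @param norms a `feature_norms` or a path readable by
#'   [read_feature_norms()].
#' @param aliases optional alias table (named vector or TSV path; see
#'   [match_concepts()]).
#' @return list with elements `congruent`, `incongruent` (one-sample
#'   `rsa_cluster_test`s), `difference` (paired test, congruent minus
#'   incongruent subtracted as incongruent - congruent so positive mass
#'   means stronger incongruent fit), `fits` (per condition) and
#'   `excluded_subjects`.
#' @export
run_semantic_analysis <- function(subjects, norms, aliases = NULL,
                                  alpha = 0.01, n_perm = 10000, seed,
                                  tail = "two",
                                  baseline_window = c(-200, 0),
                                  ptp_threshold_uv = 200,
                                  zvar_threshold = 4, out_dir = NULL) {
  if (is.character(norms)) norms <- read_feature_norms(norms)
  if (is.character(aliases)) aliases <- read_alias_table(aliases)
  if (length(subjects) < 3L) {
    stop_scenersa("need >= 3 subjects", class = "scenersa_inference_error")
  }
  fits <- list(congruent = list(), incongruent = list())
  excluded <- character(0)
  for (s in subjects) {
    prep <- prepare_subject(s, baseline_window, ptp_threshold_uv,
                            zvar_threshold)
    sid <- prep$epochs$subject_id
    matches <- match_concepts(prep$epochs$trials, norms, aliases)
    sub_fit <- tryCatch({
      lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond) {
        model <- build_semantic_rdm(prep$epochs$trials, matches, norms, cond)
        rsa_timeseries(prep$series, model, subject_id = sid)
      })
    }, scenersa_rdm_error = function(e) {
      warning("subject ", sid, " excluded from semantic analysis: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(sub_fit)) {
      excluded <- c(excluded, sid)
    } else {
      fits$congruent <- c(fits$congruent, list(sub_fit$congruent))
      fits$incongruent <- c(fits$incongruent, list(sub_fit$incongruent))
    }
  }
  if (length(fits$congruent) < 3L) {
    stop_scenersa("fewer than 3 subjects usable for the semantic analysis",
                  class = "scenersa_inference_error")
  }
  rhos_con <- stack_rsa(fits$congruent)
  rhos_incon <- stack_rsa(fits$incongruent)
  res <- list(
    congruent = signflip_cluster_test(rhos_con, alpha = alpha,
                                      n_perm = n_perm, seed = seed,
                                      tail = tail),
    incongruent = signflip_cluster_test(rhos_incon, alpha = alpha,
                                        n_perm = n_perm, seed = seed,
                                        tail = tail),
    difference = paired_cluster_test(rhos_incon, rhos_con,
                                     alpha = alpha, n_perm = n_perm,
                                     seed = seed, tail = tail),
    fits = fits,
    excluded_subjects = excluded
  )
  if (length(excluded)) {
    message(length(excluded), " subject(s) excluded from semantic analysis: ",
            paste(excluded, collapse = ", "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(out_dir, "rsa_timeseries_semantic.tsv")
    write_rsa_tsv(fits$congruent, tsv, model = "semantic",
                  condition = "congruent")
    write_rsa_tsv(fits$incongruent, tsv, model = "semantic",
                  condition = "incongruent", append = TRUE)
    params <- list(analysis = "semantic", alpha = alpha, n_perm = n_perm,
                   seed = seed, tail = tail,
                   baseline_window = baseline_window,
                   ptp_threshold_uv = ptp_threshold_uv,
                   zvar_threshold = zvar_threshold)
    prov <- pipeline_provenance(params, subjects,
                                extra = list(excluded_subjects = excluded))
    write_cluster_report(res$congruent,
                         file.path(out_dir, "clusters_semantic_congruent.json"),
                         model = "semantic", condition = "congruent",
                         extra = prov)
    write_cluster_report(res$incongruent,
                         file.path(out_dir,
                                   "clusters_semantic_incongruent.json"),
                         model = "semantic", condition = "incongruent",
                         extra = prov)
    write_cluster_report(res$difference,
                         file.path(out_dir, "clusters_semantic_difference.json"),
                         model = "semantic",
                         condition = "incongruent - congruent", extra = prov)
  }
  res
}

#' Correlate congruency and semantic-difference time courses
#'
#' Computes the group-mean congruency model fit per timepoint and the
#' group-mean difference of semantic model fits (incongruent minus
#' congruent), and Pearson-correlates the two curves, optionally inside a
#' closed ms window.
#'
#' @param congruency an `rsa_cluster_test` from
#'   [run_congruency_analysis()].
#' @param semantic result list from [run_semantic_analysis()] (or two
#'   `rsa_cluster_test`s passed as `semantic_congruent` /
#'   `semantic_incongruent`).
#' @param semantic_congruent,semantic_incongruent alternative to
#'   `semantic`.
#' @param window optional `c(start_ms, end_ms)`.
#' @param out_dir optional; writes `correlation.json`.
#' @return list with `r`, `p`, `n` and `window`.
#' @export
run_correlation_analysis <- function(congruency, semantic = NULL,
                                     semantic_congruent = semantic$congruent,
                                     semantic_incongruent =
                                       semantic$incongruent,
                                     window = NULL, out_dir = NULL) {
  if (!isTRUE(all.equal(congruency$times, semantic_congruent$times)) ||
      !isTRUE(all.equal(congruency$times, semantic_incongruent$times))) {
    stop_scenersa("analyses have different time axes",
                  class = "scenersa_axis_error")
  }
  x <- colMeans(congruency$rho)
  y <- colMeans(semantic_incongruent$rho) - colMeans(semantic_congruent$rho)
  res <- timecourse_correlation(x, y, times = congruency$times,
                                window = window)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(r = res$r, p = res$p, n_timepoints = res$n,
           window_ms = window %||% "full epoch"),
      file.path(out_dir, "correlation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
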