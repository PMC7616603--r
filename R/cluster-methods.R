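#' @export
print.rsa_cluster_test <- function(x, ...) {
  cat(sprintf("<rsa_cluster_test> %s sign-flip cluster-mass permutation test\n",
              x$type))
  cat(sprintf("  %d subjects x %d timepoints (%g..%g ms)\n",
              nrow(x$rho), length(x$times), x$times[1L],
              x$times[length(x$times)]))
  cat(sprintf("  cluster-forming alpha %g (%s-tailed, |t| > %.3f), %d permutations, seed %d\n",
              x$alpha, if (x$tail == "two") "two" else "one", x$threshold,
              x$n_perm, x$seed))
  if (nrow(x$clusters) == 0L) {
    cat("  no suprathreshold clusters\n")
  } else {
    cl <- x$clusters
    for (k in seq_len(nrow(cl))) {
      cat(sprintf("  cluster %d: %g-%g ms, mass %.2f, p = %.4g\n", k,
                  cl$start_time[k], cl$end_time[k], cl$mass[k],
                  cl$p_value[k]))
    }
  }
  invisible(x)
}

#' Summarise a cluster permutation test
#'
#' @param object an `rsa_cluster_test`.
#' @param ... unused.
#' @return the cluster table (data.frame) with start/end times, signed
#'   masses and permutation p values, invisibly printed.
#' @export
summary.rsa_cluster_test <- function(object, ...) {
  print(object)
  invisible(object$clusters)
}

#' Group-mean model-fit time course of a fitted cluster test
#'
#' @param object an `rsa_cluster_test`.
#' @param ... unused.
#' @return named numeric vector: mean Spearman rho (or rho difference, for
#'   paired tests) per timepoint.
#' @export
coef.rsa_cluster_test <- function(object, ...) {
  stats::setNames(colMeans(object$rho), object$times)
}

#' Plot a fitted RSA cluster test
#'
#' Line plot of the group-mean model fit with +/-1 SEM shading and
#' horizontal bars marking clusters with p <= `sig_level`.
#'
#' @param x an `rsa_cluster_test`.
#' @param sig_level significance level for marking clusters (default 0.05).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rsa_cluster_test <- function(x, sig_level = 0.05, ...) {
  m <- colMeans(x$rho)
  sem <- apply(x$rho, 2L, stats::sd) / sqrt(nrow(x$rho))
  ylim <- range(m + sem, m - sem, 0)
  graphics::plot(x$times, m, type = "n", xlab = "time (ms)",
                 ylab = if (x$type == "paired") {
                   "mean rho difference"
                 } else {
                   "mean Spearman rho"
                 },
                 ylim = ylim, ...)
  graphics::polygon(c(x$times, rev(x$times)), c(m + sem, rev(m - sem)),
                    col = grDevices::adjustcolor("grey60", alpha.f = 0.4),
                    border = NA)
  graphics::abline(h = 0, lty = 3)
  graphics::lines(x$times, m, lwd = 2)
  cl <- x$clusters[x$clusters$p_value <= sig_level, , drop = FALSE]
  if (nrow(cl)) {
    y0 <- ylim[1L] + 0.02 * diff(ylim)
    graphics::segments(cl$start_time, y0, cl$end_time, y0, lwd = 4)
  }
  invisible(x)
}

#' Export a cluster test report as JSON
#'
#' Writes the cluster table together with the full inferential provenance
#' (model/contrast name, alpha, tail, permutation count, seed and any extra
#' provenance fields), deterministically formatted so identical analyses
#' yield byte-identical files.
#'
#' @param fit an `rsa_cluster_test`.
#' @param path output path.
#' @param model name of the model RDM or contrast tested.
#' @param condition condition analysed, or contrast description.
#' @param extra named list of additional provenance fields (hashes, package
#'   version, ...).
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(fit, path, model = "", condition = "",
                                 extra = list()) {
  cl <- fit$clusters
  report <- c(list(
    model = model,
    condition = condition,
    n_subjects = nrow(fit$rho),
    alpha_cluster_forming = fit$alpha,
    tail = fit$tail,
    n_permutations = fit$n_perm,
    seed = fit$seed,
    clusters = lapply(seq_len(nrow(cl)), function(k) {
      list(start_ms = cl$start_time[k], end_ms = cl$end_time[k],
           mass = cl$mass[k], p_value = cl$p_value[k])
    })
  ), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write per-subject RSA time series as TSV
#'
#' Long-format table with columns subject_id, time_ms, model, condition,
#' rho — the tabular result format of the pipeline.
#'
#' @param fits list of `rsa_timeseries`.
#' @param path output path.
#' @param model model name recorded in the `model` column.
#' @param condition condition recorded in the `condition` column.
#' @param append append to an existing file (default FALSE).
#' @return `path`, invisibly.
#' @export
write_rsa_tsv <- function(fits, path, model = "", condition = "all",
                          append = FALSE) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    data.frame(subject_id = f$subject_id, time_ms = f$times, model = model,
               condition = condition, rho = f$rho, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(path)
}
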