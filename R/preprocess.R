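#' Baseline-correct epoched EEG
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (a closed interval evaluated on the time grid) from the whole
#' epoch. The standard pre-stimulus window is -200..0 ms. The operation is
#' idempotent: re-applying it with the same window leaves the data unchanged
#' (to floating-point precision).
#'
#' @param epochs an `epoch_set`.
#' @param window_start_ms,window_end_ms closed baseline window in ms; must
#'   contain at least one grid timepoint.
#' @return a corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window_start_ms = -200,
                             window_end_ms = 0) {
  validate_epoch_set(epochs)
  idx <- window_idx(epochs$times, window_start_ms, window_end_ms)
  base <- epochs$data[, , idx, drop = FALSE]
  mu <- rowMeans(base, dims = 2L)            # trial x channel means
  epochs$data <- epochs$data - as.vector(mu) # recycles over the time axis
  epochs
}

#' Flag noisy trials by amplitude and variance heuristics
#'
#' A deterministic stand-in for manual artifact screening. A trial is
#' flagged when (a) its maximum peak-to-peak amplitude over channels exceeds
#' `ptp_threshold_uv`, or (b) the z-score (across trials) of its
#' log-variance exceeds `zvar_threshold`. Flagged trials get `keep = FALSE`
#' in the trial table; amplitudes are never modified. Trials already marked
#' `keep = FALSE` are left out of the z-scoring reference set.
#'
#' @param epochs an `epoch_set`.
#' @param ptp_threshold_uv peak-to-peak threshold in microvolts (default 200).
#' @param zvar_threshold log-variance z-score threshold (default 4).
#' @return the `epoch_set` with updated keep flags; the number of newly
#'   removed trials is reported with `message()`.
#' @export
reject_noisy_trials <- function(epochs, ptp_threshold_uv = 200,
                                zvar_threshold = 4) {
  validate_epoch_set(epochs)
  stopifnot(ptp_threshold_uv > 0, zvar_threshold > 0)
  keep0 <- epochs$trials$keep
  idx <- which(keep0)
  n <- length(idx)

  # max over channels of within-channel peak-to-peak range
  ptp <- vapply(idx, function(i) {
    x <- epochs$data[i, , , drop = FALSE]
    dim(x) <- dim(epochs$data)[2:3]
    max(apply(x, 1L, function(ch) diff(range(ch))))
  }, numeric(1L))

  # per-trial variance pooled over channels and timepoints
  v <- vapply(idx, function(i) stats::var(as.vector(epochs$data[i, , ])),
              numeric(1L))
  lv <- log(pmax(v, .Machine$double.xmin))
  s <- stats::sd(lv)
  z <- if (n > 1L && s > 0) (lv - mean(lv)) / s else rep(0, n)

  bad <- ptp > ptp_threshold_uv | z > zvar_threshold
  if (all(bad)) {
    stop_scenersa("all ", n, " trials rejected; analysis impossible ",
                  "(thresholds ptp=", ptp_threshold_uv, " uV, zvar=",
                  zvar_threshold, ")", class = "scenersa_rejection_error")
  }
  epochs$trials$keep[idx[bad]] <- FALSE
  message(sum(bad), " of ", n, " trials flagged as noisy (",
          sprintf("%.1f", 100 * sum(bad) / n), "%)")
  epochs
}
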