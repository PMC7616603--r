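#' Conditions recognised in trial metadata
#' @keywords internal
CONDITIONS <- c("congruent", "incongruent")

#' Construct an epoched EEG data set
#'
#' An `epoch_set` bundles one participant's epoched EEG — a numeric array
#' indexed (trial, channel, timepoint), amplitudes in microvolts — with a
#' millisecond time axis, channel names, the sampling frequency and a trial
#' table describing the scene-object design.
#'
#' @param subject_id single string identifying the participant.
#' @param data numeric array, trials x channels x timepoints, in microvolts.
#' @param times numeric vector of timepoints in ms, strictly increasing with
#'   uniform spacing.
#' @param channel_names character vector, one name per channel.
#' @param sfreq sampling frequency in Hz; must be consistent with the spacing
#'   of `times`.
#' @param trials a trial table as returned by [trial_table()], one row per
#'   trial in `data`.
#' @return an object of class `epoch_set`.
#' @seealso [read_epochs()], [write_epochs()], [baseline_correct()],
#'   [reject_noisy_trials()]
#' @export
epoch_set <- function(subject_id, data, times, channel_names, sfreq, trials) {
  x <- structure(
    list(
      subject_id = as.character(subject_id),
      data = data,
      times = as.numeric(times),
      channel_names = as.character(channel_names),
      sfreq = as.numeric(sfreq),
      trials = trials
    ),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

#' Validate an epoch_set against its invariants
#'
#' Checks array/axis shape agreement, uniform time spacing consistent with
#' the sampling frequency, finiteness of the data, and the trial-table
#' invariants. Called by every constructor and reader; errors name the
#' offending component.
#'
#' @param x an `epoch_set`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_epoch_set <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  if (is.null(d) || length(d) != 3L) {
    stop_scenersa("data must be a 3-d array (trial x channel x timepoint)",
                  class = "scenersa_shape_error")
  }
  if (d[1L] < 1L) {
    stop_scenersa("epoch_set must contain at least one trial",
                  class = "scenersa_shape_error")
  }
  validate_trial_table(x$trials)
  if (nrow(x$trials) != d[1L]) {
    stop_scenersa("trials table has ", nrow(x$trials), " rows but data has ",
                  d[1L], " trials", class = "scenersa_shape_error")
  }
  if (length(x$channel_names) != d[2L]) {
    stop_scenersa("channel_names length ", length(x$channel_names),
                  " does not match data channel axis ", d[2L],
                  class = "scenersa_shape_error")
  }
  if (length(x$times) != d[3L]) {
    stop_scenersa("times length ", length(x$times),
                  " does not match data time axis ", d[3L],
                  class = "scenersa_shape_error")
  }
  if (length(x$times) > 1L) {
    dt <- diff(x$times)
    if (any(dt <= 0)) {
      stop_scenersa("times must be strictly increasing",
                    class = "scenersa_time_axis_error")
    }
    if (max(dt) - min(dt) > 1e-9) {
      stop_scenersa("times must be uniformly spaced (spacing varies by more ",
                    "than 1e-9 ms)", class = "scenersa_time_axis_error")
    }
    step_from_sfreq <- 1000 / x$sfreq
    if (abs(dt[1L] - step_from_sfreq) > 1e-6) {
      stop_scenersa("time step ", signif(dt[1L], 8), " ms inconsistent with ",
                    "sfreq ", x$sfreq, " Hz (expected ",
                    signif(step_from_sfreq, 8), " ms)",
                    class = "scenersa_time_axis_error")
    }
  }
  if (!all(is.finite(x$data))) {
    bad <- which(!is.finite(x$data), arr.ind = TRUE)[1L, ]
    stop_scenersa("non-finite amplitude at trial ", bad[1L], ", channel ",
                  bad[2L], ", timepoint ", bad[3L],
                  class = "scenersa_data_error")
  }
  invisible(x)
}

#' Construct a per-trial metadata table
#'
#' @param trial_id integer trial identifiers, unique.
#' @param scene_id character scene identifiers.
#' @param object_label character object concept labels.
#' @param condition character, `"congruent"` or `"incongruent"` per trial.
#' @param keep logical; `FALSE` marks trials excluded from analysis
#'   (defaults to all `TRUE`).
#' @return a `data.frame` with class `trial_table`.
#' @export
trial_table <- function(trial_id, scene_id, object_label, condition,
                        keep = rep(TRUE, length(trial_id))) {
  tab <- data.frame(
    trial_id = as.integer(trial_id),
    scene_id = as.character(scene_id),
    object_label = as.character(object_label),
    condition = as.character(condition),
    keep = as.logical(keep),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("trial_table", "data.frame")
  validate_trial_table(tab)
  tab
}

#' @rdname trial_table
#' @param tab a trial table to validate.
#' @export
validate_trial_table <- function(tab) {
  need <- c("trial_id", "scene_id", "object_label", "condition", "keep")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_scenersa("trial table lacks column(s): ", paste(miss, collapse = ", "),
                  class = "scenersa_trials_error")
  }
  if (anyDuplicated(tab$trial_id)) {
    stop_scenersa("trial_id values must be unique",
                  class = "scenersa_trials_error")
  }
  bad <- tab$keep & !(tab$condition %in% CONDITIONS)
  if (any(bad)) {
    stop_scenersa("unknown condition '", tab$condition[which(bad)[1L]],
                  "' in trial row ", which(bad)[1L],
                  class = "scenersa_trials_error")
  }
  if (any(is.na(tab$keep))) {
    stop_scenersa("keep flag must be TRUE/FALSE for every trial",
                  class = "scenersa_trials_error")
  }
  invisible(tab)
}

#' Kept trials of an epoch_set
#' @param epochs an `epoch_set`.
#' @return integer row indices of trials with `keep = TRUE`.
#' @keywords internal
kept_idx <- function(epochs) which(epochs$trials$keep)

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> subject", x$subject_id, "\n")
  cat(sprintf("  %d trials (%d kept) x %d channels x %d timepoints\n",
              d[1L], sum(x$trials$keep), d[2L], d[3L]))
  cat(sprintf("  time %g..%g ms, step %g ms (%g Hz)\n",
              x$times[1L], x$times[length(x$times)],
              if (length(x$times) > 1) diff(x$times[1:2]) else NA_real_,
              x$sfreq))
  n_cond <- table(factor(x$trials$condition[x$trials$keep],
                         levels = CONDITIONS))
  cat(sprintf("  kept: %d congruent / %d incongruent\n",
              n_cond[["congruent"]], n_cond[["incongruent"]]))
  invisible(x)
}

#' Indices of grid timepoints inside a closed window
#'
#' @param times numeric time axis in ms.
#' @param window_start_ms,window_end_ms closed window bounds in ms.
#' @return integer indices of timepoints with
#'   `window_start_ms <= t <= window_end_ms`.
#' @keywords internal
window_idx <- function(times, window_start_ms, window_end_ms) {
  if (window_end_ms < window_start_ms) {
    stop_scenersa("empty window: end ", window_end_ms, " ms before start ",
                  window_start_ms, " ms", class = "scenersa_window_error")
  }
  idx <- which(times >= window_start_ms - 1e-9 & times <= window_end_ms + 1e-9)
  if (!length(idx)) {
    stop_scenersa("window [", window_start_ms, ", ", window_end_ms,
                  "] ms contains no grid timepoints",
                  class = "scenersa_window_error")
  }
  idx
}
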