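#' Per-timepoint neural RDM series
#'
#' At each timepoint the multivariate pattern of a trial is its vector of
#' channel amplitudes; the dissimilarity between two trials is the
#' correlation distance (1 - Pearson) between their patterns. One RDM per
#' timepoint is computed over all kept trials, using every channel. A
#' constant pattern (zero variance across channels) is an error naming the
#' trial and timepoint, since real or simulated EEG should never be exactly
#' flat and silence there would hide pipeline bugs.
#'
#' @param epochs an `epoch_set` with >= 2 kept trials and >= 3 channels.
#' @return an object of class `rdm_series`: list with `times` (ms),
#'   `labels` (trial ids) and `array` (item x item x time dissimilarities).
#' @export
neural_rdm_series <- function(epochs) {
  validate_epoch_set(epochs)
  idx <- kept_idx(epochs)
  n <- length(idx)
  if (n < 2L) {
    stop_scenersa("need >= 2 kept trials for a neural RDM",
                  class = "scenersa_rdm_error")
  }
  if (dim(epochs$data)[2L] < 3L) {
    stop_scenersa("need >= 3 channels for correlation-distance patterns",
                  class = "scenersa_rdm_error")
  }
  nt <- length(epochs$times)
  labels <- as.character(epochs$trials$trial_id[idx])
  arr <- array(NA_real_, c(n, n, nt))
  for (t in seq_len(nt)) {
    pat <- t(epochs$data[idx, , t])      # channels x trials
    sds <- apply(pat, 2L, stats::sd)
    if (any(sds == 0)) {
      bad <- which(sds == 0)[1L]
      stop_scenersa("constant channel pattern for trial ", labels[bad],
                    " at timepoint ", epochs$times[t], " ms",
                    class = "scenersa_distance_error")
    }
    d <- 1 - stats::cor(pat)
    d[d < 0] <- 0
    d[d > 2] <- 2
    diag(d) <- 0
    d <- (d + t(d)) / 2                  # enforce exact symmetry
    arr[, , t] <- d
  }
  structure(list(times = epochs$times, labels = labels, array = arr),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("<rdm_series> %d timepoints, %d x %d items\n",
              length(x$times), length(x$labels), length(x$labels)))
  cat(sprintf("  time %g..%g ms\n", x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Extract the RDM at one timepoint
#' @param series an `rdm_series`.
#' @param t timepoint index (1-based).
#' @return an `rdm` with metric `"correlation"`.
#' @export
rdm_at <- function(series, t) {
  stopifnot(t >= 1L, t <= length(series$times))
  rdm(series$array[, , t], series$labels, metric = "correlation")
}

#' Subset a neural RDM series to a label set
#'
#' Restricts every timepoint's RDM to the requested trial ids, in the
#' requested order — used to align the neural series with a per-condition
#' semantic model RDM built over a subset of trials.
#'
#' @param series an `rdm_series`.
#' @param labels trial ids to retain (character or coercible), all present
#'   in `series$labels`; at least 2.
#' @return the restricted `rdm_series`.
#' @export
subset_rdm_series <- function(series, labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop_scenersa("an RDM needs at least 2 items",
                  class = "scenersa_rdm_error")
  }
  pos <- match(labels, series$labels)
  if (anyNA(pos)) {
    stop_scenersa("unknown label(s): ",
                  paste(labels[is.na(pos)], collapse = ", "),
                  class = "scenersa_rdm_error")
  }
  structure(list(times = series$times, labels = labels,
                 array = series$array[pos, pos, , drop = FALSE]),
            class = "rdm_series")
}

#' Matrix of lower-triangle vectorisations of a series
#' @param series an `rdm_series`.
#' @return numeric matrix, pairs x timepoints.
#' @keywords internal
series_triangles <- function(series) {
  n <- length(series$labels)
  lt <- lower.tri(matrix(0, n, n))
  apply(series$array, 3L, function(m) m[lt])
}

#' Cache a neural RDM series inside an HDF5 container
#'
#' Writes the series under `/neural_rdms` (item x item x time), with
#' `/neural_rdm_times` and `/neural_rdm_labels`, keyed by a content hash of
#' the source epochs so stale caches are detectable.
#'
#' @param series an `rdm_series`.
#' @param path HDF5 file (created if absent).
#' @param epochs_hash content hash of the epochs the series was computed
#'   from (see [epochs_content_hash()]).
#' @return `path`, invisibly.
#' @export
write_rdm_series <- function(series, path, epochs_hash = "") {
  if (!file.exists(path)) rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)$name
  for (ds in c("neural_rdms", "neural_rdm_times", "neural_rdm_labels")) {
    if (ds %in% present) rhdf5::h5delete(path, ds)
  }
  rhdf5::h5write(series$array, path, "neural_rdms", level = 0)
  rhdf5::h5write(series$times, path, "neural_rdm_times", level = 0)
  rhdf5::h5write(series$labels, path, "neural_rdm_labels", level = 0)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs_hash, fid, "neural_rdm_epochs_hash")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a cached neural RDM series
#' @param path HDF5 file written by [write_rdm_series()].
#' @return list with the `rdm_series` and the stored `epochs_hash`.
#' @export
read_rdm_series <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  series <- structure(
    list(times = as.numeric(rhdf5::h5read(path, "neural_rdm_times")),
         labels = as.character(rhdf5::h5read(path, "neural_rdm_labels")),
         array = rhdf5::h5read(path, "neural_rdms")),
    class = "rdm_series"
  )
  attrs <- rhdf5::h5readAttributes(path, "/")
  list(series = series,
       epochs_hash = as.character(attrs$neural_rdm_epochs_hash %||% ""))
}

#' Content hash of an epoch_set
#'
#' Digest of the amplitudes, time axis, channels and trial table, used to
#' key cached neural RDM series.
#'
#' @param epochs an `epoch_set`.
#' @return a hex string.
#' @export
epochs_content_hash <- function(epochs) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(list(epochs$data, epochs$times, epochs$channel_names,
                 epochs$sfreq, as.data.frame(epochs$trials)),
            con, version = 2L)
  close(con)
  unname(tools::md5sum(tmp))
}
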