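#' Write an epoch_set to the HDF5 epoch container
#'
#' Layout: datasets `/data` (trial x channel x time, float64), `/times` (ms),
#' `/channels` (strings), a compound dataset `/trials` with columns trial_id,
#' scene_id, object_label, condition, keep (integer 0/1), and root attributes
#' `subject_id` and `sfreq`. Amplitudes are stored as 64-bit floats so
#' [read_epochs()] reproduces the input bit-exactly.
#'
#' @param epochs a valid `epoch_set`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  validate_epoch_set(epochs)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_scenersa("cannot write epochs: directory does not exist: ", dir,
                  class = "scenersa_io_error")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  # chunk+no compression keeps writes fast and float64 exact
  rhdf5::h5write(epochs$data, path, "data", level = 0)
  rhdf5::h5write(epochs$times, path, "times", level = 0)
  rhdf5::h5write(epochs$channel_names, path, "channels", level = 0)
  tab <- as.data.frame(epochs$trials)
  tab$keep <- as.integer(tab$keep)
  rhdf5::h5write(tab, path, "trials")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs$subject_id, fid, "subject_id")
  rhdf5::h5writeAttribute(epochs$sfreq, fid, "sfreq")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read an epoch_set from the HDF5 epoch container
#'
#' Inverse of [write_epochs()]. All `epoch_set` invariants are re-checked on
#' load; a container whose trial table and data array disagree in length, or
#' that contains non-finite amplitudes or unknown condition strings, is
#' rejected with a diagnostic naming the offending dataset or row.
#'
#' @param path path to a container written by [write_epochs()] (or any file
#'   following the same layout).
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) {
    stop_scenersa("no such file: ", path, class = "scenersa_io_error")
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)$name
  for (ds in c("data", "times", "channels", "trials")) {
    if (!ds %in% present) {
      stop_scenersa("container missing dataset /", ds,
                    class = "scenersa_io_error")
    }
  }
  data <- rhdf5::h5read(path, "data")
  times <- as.numeric(rhdf5::h5read(path, "times"))
  channels <- as.character(rhdf5::h5read(path, "channels"))
  raw_tab <- rhdf5::h5read(path, "trials")
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$subject_id) || is.null(attrs$sfreq)) {
    stop_scenersa("container missing subject_id/sfreq root attributes",
                  class = "scenersa_io_error")
  }
  tab <- trial_table(
    trial_id = raw_tab$trial_id,
    scene_id = raw_tab$scene_id,
    object_label = raw_tab$object_label,
    condition = raw_tab$condition,
    keep = as.integer(raw_tab$keep) != 0L
  )
  epoch_set(
    subject_id = as.character(attrs$subject_id),
    data = data,
    times = times,
    channel_names = channels,
    sfreq = as.numeric(attrs$sfreq),
    trials = tab
  )
}

#' Write a trial table as TSV
#' @param trials a trial table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  utils::write.table(as.data.frame(trials), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from TSV
#' @param path TSV with columns trial_id, scene_id, object_label, condition,
#'   keep.
#' @return a `trial_table`.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  trial_table(tab$trial_id, tab$scene_id, tab$object_label, tab$condition,
              as.logical(tab$keep))
}
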