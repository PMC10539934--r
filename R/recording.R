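#' Construct a continuous multichannel EEG recording
#'
#' The basic container for continuous data: a channels x samples numeric
#' matrix in microvolts with a sampling rate and subject metadata.
#'
#' @param data Numeric matrix, channels x samples (muV). Row names, if
#'   present, must agree with `channels`.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels drawn from the 19-label
#'   10-20 montage ([MONTAGE_19]); defaults to the full montage.
#' @param subject_id Subject identifier.
#' @param group Group label (e.g. `"HC"` or `"MCI"`), or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = MONTAGE_19,
                          subject_id = "s01", group = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (nrow(data) != length(channels)) {
    stop("nrow(data) (", nrow(data), ") != number of channels (",
         length(channels), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  check_channels(channels)
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         subject_id = subject_id, group = group),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Seconds of data.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct an epoch set
#'
#' Fixed-length epochs, the unit of all downstream estimation. Stored as a
#' 3-d array epoch x channel x sample.
#'
#' @param epochs Numeric array, epoch x channel x sample.
#' @param fs Sampling rate (Hz).
#' @param epoch_length Epoch length in seconds; every epoch must hold exactly
#'   `round(fs * epoch_length)` samples.
#' @param channels Channel labels.
#' @param subject_id,group Provenance carried from the source recording.
#' @param kept_indices Indices of the source epochs retained (provenance).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, epoch_length, channels = MONTAGE_19,
                      subject_id = "s01", group = NA_character_,
                      kept_indices = seq_len(dim(epochs)[1])) {
  stopifnot(length(dim(epochs)) == 3L)
  n_samp <- round(fs * epoch_length)
  if (dim(epochs)[3] != n_samp) {
    stop("each epoch must hold round(fs * epoch_length) = ", n_samp,
         " samples, got ", dim(epochs)[3])
  }
  if (dim(epochs)[1] < 1L) stop("epoch count must be >= 1")
  if (dim(epochs)[2] != length(channels)) stop("channel dimension mismatch")
  check_channels(channels)
  structure(
    list(epochs = epochs, fs = fs, epoch_length = epoch_length,
         channels = channels, subject_id = subject_id, group = group,
         kept_indices = kept_indices),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<epoch_set> %s [%s]: %d epochs x %d ch x %d samples (%g s @ %g Hz)\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$epoch_length, x$fs))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es An `epoch_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(es) dim(es$epochs)[1]

#' Serialize an epoch set to a text file with a JSON sidecar
#'
#' Writes the epoch array as a TSV (one row per epoch x channel, one column
#' per sample) plus a `<path>.json` sidecar holding sampling rate, epoch
#' length, channel order and provenance, so the pair fully reconstructs the
#' object.
#'
#' @param es An [epoch_set()].
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(es, path) {
  d <- dim(es$epochs)
  flat <- matrix(aperm(es$epochs, c(3L, 2L, 1L)), nrow = d[1] * d[2],
                 byrow = TRUE)
  idx <- expand.grid(channel = es$channels, epoch = seq_len(d[1]),
                     stringsAsFactors = FALSE)
  out <- cbind(idx[, c("epoch", "channel")], as.data.frame(flat))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fs = es$fs, epoch_length = es$epoch_length, channels = es$channels,
         subject_id = es$subject_id, group = es$group,
         kept_indices = es$kept_indices, n_epochs = d[1], n_samples = d[3]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path TSV path (the `<path>.json` sidecar must exist).
#' @return An [epoch_set()].
#' @export
read_epoch_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  arr <- array(NA_real_, c(meta$n_epochs, length(meta$channels),
                           meta$n_samples))
  for (r in seq_len(nrow(tab))) {
    e <- tab$epoch[r]
    ch <- match(tab$channel[r], meta$channels)
    arr[e, ch, ] <- vals[r, ]
  }
  epoch_set(arr, meta$fs, meta$epoch_length, channels = meta$channels,
            subject_id = meta$subject_id, group = meta$group,
            kept_indices = meta$kept_indices)
}

#' Concatenate the epochs of one channel into a single series
#'
#' Used by the complexity module, which operates on the concatenated
#' artifact-free epochs of each channel (100 s = 20,000 samples under the
#' default 50 x 2-s selection at 200 Hz).
#'
#' @param es An `epoch_set`.
#' @param channel Channel label or index.
#' @return Numeric vector.
#' @export
concat_channel <- function(es, channel) {
  if (is.character(channel)) channel <- match(channel, es$channels)
  if (is.na(channel)) stop("unknown channel")
  m <- es$epochs[, channel, , drop = FALSE]     # epochs x 1 x samples
  as.vector(aperm(m, c(3L, 1L, 2L)))            # epoch-major concatenation
}
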