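# Minimal European Data Format (EDF) I/O: ASCII header plus 16-bit
# little-endian samples with linear physical/digital scaling. Enough to
# round-trip the recordings this package produces and to ingest standard
# 19-channel clinical exports (reference channels such as A1/A2 are
# ignored on read).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' One data record per second; the recording is truncated to whole seconds.
#' Samples are quantised to 16 bits over a symmetric physical range.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer fs")
  fs <- as.integer(round(fs))
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(data)
  pmax_ <- max(1e-6, max(abs(data)))
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32767L; dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)

  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(.edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put(paste("X X X", rec$subject_id), 80)
  put(paste("Startdate 01-JAN-2000 X X X group", rec$group), 80)
  put("01.01.00", 8)
  put("00.00.00", 8)
  put(header_bytes, 8)
  put("", 44)
  put(n_rec, 8)
  put("1", 8)
  put(ns, 4)
  for (ch in rec$channels) put(paste("EEG", ch), 16)
  for (i in seq_len(ns)) put("AgAgCl electrode", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(formatC(phys_min, format = "g", digits = 6), 8)
  for (i in seq_len(ns)) put(formatC(phys_max, format = "g", digits = 6), 8)
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(fs, 8)
  for (i in seq_len(ns)) put("", 32)

  dig <- round((data - phys_min) * scale + dig_min)
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[s, idx]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Channel labels are matched case-insensitively against the 19-label 10-20
#' montage after stripping an optional `EEG` prefix and reference suffixes
#' (e.g. `EEG Fp1-A1` matches `Fp1`); unmatched channels (EOG, ECG, A1/A2
#' references, annotations) are dropped.
#'
#' @param path EDF file path.
#' @param subject_id,group Metadata for the returned recording; defaults to
#'   the file name and `NA`.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL,
                     group = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  gets <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  gets(8)                       # version
  gets(80); gets(80); gets(8); gets(8)
  gets(8)                       # header bytes
  gets(44)
  n_rec <- as.integer(gets(8))
  rec_dur <- as.numeric(gets(8))
  ns <- as.integer(gets(4))
  labels <- vapply(seq_len(ns), function(i) gets(16), character(1))
  for (i in seq_len(ns)) gets(80)          # transducer
  for (i in seq_len(ns)) gets(8)           # dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(gets(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(gets(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(gets(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(gets(8)), numeric(1))
  for (i in seq_len(ns)) gets(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(gets(8)), integer(1))
  for (i in seq_len(ns)) gets(32)

  raw <- lapply(seq_len(ns), function(i) integer(0))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw[[s]] <- c(raw[[s]],
                    readBin(con, integer(), n = spr[s], size = 2L,
                            signed = TRUE, endian = "little"))
    }
  }

  clean <- toupper(gsub("^EEG[ _]*|[- ].*$", "", labels))
  keep <- match(clean, toupper(MONTAGE_19))
  sel <- which(!is.na(keep))
  if (!length(sel)) stop("no montage channels found in ", path)
  fs <- spr[sel[1]] / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- t(vapply(sel, function(s) {
    (raw[[s]] - dig_min[s]) * scale[s] + phys_min[s]
  }, numeric(n_rec * spr[sel[1]])))
  if (is.null(subject_id)) subject_id <- tools::file_path_sans_ext(basename(path))
  eeg_recording(data, fs, channels = MONTAGE_19[keep[sel]],
                subject_id = subject_id, group = group)
}
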