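#' Band-pass filter a continuous recording
#'
#' Zero-phase band-pass implemented as a cascade of 4th-order Butterworth
#' high-pass and low-pass sections, each applied forward-backward
#' ([filtfilt_zp()]). The cascade is numerically safer than a single 8-pole
#' band-pass when the lower edge (0.1 Hz) sits very close to DC.
#'
#' @param rec An [eeg_recording()].
#' @param f_lo,f_hi Pass-band edges in Hz; `0 <= f_lo < f_hi < fs/2`.
#'   `f_lo = 0` skips the high-pass section.
#' @param order Butterworth order per section (default 4).
#' @return A filtered `eeg_recording` of identical shape.
#' @export
bandpass_filter <- function(rec, f_lo = 0.1, f_hi = 50, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi < rec$fs / 2)) {
    stop("invalid band edges: need 0 <= f_lo < f_hi < fs/2")
  }
  lp <- butter_design(order, f_hi, rec$fs, "low")
  hp <- if (f_lo > 0) butter_design(order, f_lo, rec$fs, "high") else NULL
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- filtfilt_zp(lp, out[i, ])
    if (!is.null(hp)) x <- filtfilt_zp(hp, x)
    out[i, ] <- x
  }
  rec$data <- out
  rec
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Consecutive, non-overlapping epochs from the start of the recording; a
#' trailing partial epoch is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length Epoch length in seconds (default 2).
#' @return An [epoch_set()].
#' @export
epoch_recording <- function(rec, epoch_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_samp <- round(rec$fs * epoch_length)
  n_total <- ncol(rec$data)
  n_ep <- n_total %/% n_samp
  if (n_ep < 1L) {
    stop("recording (", n_total / rec$fs, " s) shorter than one epoch (",
         epoch_length, " s)")
  }
  arr <- array(NA_real_, dim = c(n_ep, nrow(rec$data), n_samp))
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * n_samp + 1L):(e * n_samp)
    arr[e, , ] <- rec$data[, idx]
  }
  epoch_set(arr, rec$fs, epoch_length, channels = rec$channels,
            subject_id = rec$subject_id, group = rec$group)
}

#' Flag artifact epochs by amplitude and flatline criteria
#'
#' An automated surrogate for visual artifact rejection: an epoch is bad if
#' any channel's peak-to-peak amplitude exceeds `amp_limit` (gross artifact)
#' or falls below `flat_limit` (flat/disconnected electrode).
#'
#' @param es An [epoch_set()].
#' @param amp_limit Peak-to-peak ceiling in muV (default 150).
#' @param flat_limit Peak-to-peak floor in muV (default 0.5).
#' @return Logical vector, `TRUE` for epochs to keep.
#' @export
screen_artifacts <- function(es, amp_limit = 150, flat_limit = 0.5) {
  stopifnot(inherits(es, "epoch_set"))
  if (!(amp_limit > 0 && flat_limit > 0)) stop("limits must be > 0")
  vapply(seq_len(n_epochs(es)), function(e) {
    seg <- array(es$epochs[e, , , drop = FALSE], dim = dim(es$epochs)[2:3])
    ptp <- apply(seg, 1, function(v) diff(range(v)))
    all(ptp <= amp_limit) && all(ptp >= flat_limit)
  }, logical(1))
}

#' Select the first n good epochs
#'
#' Keeps the first `n_keep` epochs flagged good, in temporal order. Errors
#' if fewer than `n_keep` good epochs are available, naming the shortfall.
#'
#' @param es An [epoch_set()].
#' @param mask Logical keep-mask as from [screen_artifacts()].
#' @param n_keep Number of epochs to retain (default 50).
#' @return An [epoch_set()] with exactly `n_keep` epochs; `kept_indices`
#'   records which source epochs survive.
#' @export
select_epochs <- function(es, mask = rep(TRUE, n_epochs(es)), n_keep = 50L) {
  stopifnot(inherits(es, "epoch_set"), length(mask) == n_epochs(es))
  good <- which(mask)
  if (length(good) < n_keep) {
    stop("only ", length(good), " artifact-free epochs available; need ",
         n_keep, " (short by ", n_keep - length(good), ") for subject ",
         es$subject_id)
  }
  keep <- good[seq_len(n_keep)]
  epoch_set(es$epochs[keep, , , drop = FALSE], es$fs, es$epoch_length,
            channels = es$channels, subject_id = es$subject_id,
            group = es$group, kept_indices = keep)
}

#' Full per-subject preprocessing
#'
#' Filter the continuous recording, cut epochs, screen artifacts, and select
#' the analysis epoch set. Filtering is applied to the continuous data before
#' epoching, never per epoch.
#'
#' @param rec An [eeg_recording()].
#' @param f_lo,f_hi Band-pass edges (Hz).
#' @param epoch_length Epoch length in seconds.
#' @param n_keep Number of artifact-free epochs to retain; `NULL` keeps all
#'   good epochs.
#' @param amp_limit,flat_limit Artifact screening thresholds (muV).
#' @return An [epoch_set()].
#' @export
preprocess_subject <- function(rec, f_lo = 0.1, f_hi = 50, epoch_length = 2,
                               n_keep = 50L, amp_limit = 150,
                               flat_limit = 0.5) {
  filt <- bandpass_filter(rec, f_lo, f_hi)
  es <- epoch_recording(filt, epoch_length)
  mask <- screen_artifacts(es, amp_limit, flat_limit)
  if (is.null(n_keep)) n_keep <- sum(mask)
  select_epochs(es, mask, n_keep)
}
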