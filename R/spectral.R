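# Multitaper spectral estimation with discrete prolate spheroidal sequences
# (DPSS). Tapers are obtained as eigenvectors of the standard symmetric
# tridiagonal commuting matrix and cached per (N, NW, K).

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-half-bandwidth
#' product `nw` via the tridiagonal eigenproblem. Tapers are unit-energy and
#' sign-fixed so that each taper's mean (or first nonzero moment) is
#' positive.
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product (default 2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  if (k < 1) stop("bandwidth too small: no tapers requested")
  if (k > n) stop("cannot build more tapers than samples")
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    if (abs(s) < 1e-12) s <- tap[2, j] - tap[1, j]  # odd tapers: fix slope
    if (s < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density of an epoch set
#'
#' Per-epoch DPSS multitaper spectra, averaged over tapers and epochs.
#' One-sided density in muV^2/Hz: the integral of the estimate over
#' `[0, fs/2]` approximates the signal variance.
#'
#' @param es An [epoch_set()].
#' @param nw Time-half-bandwidth product (default 2, i.e. bandwidth
#'   `2 * nw / epoch_length` Hz total; 3 tapers).
#' @param k Number of tapers, default `2 * nw - 1`.
#' @return An object of class `psd_estimate`: list with `freqs` (Hz),
#'   `power` (channel x frequency matrix, muV^2/Hz), `n_epochs`, `fs`,
#'   `channels`.
#' @export
multitaper_psd <- function(es, nw = 2, k = 2 * nw - 1) {
  stopifnot(inherits(es, "epoch_set"))
  d <- dim(es$epochs)
  n <- d[3]
  tap <- dpss_tapers(n, nw, k)
  n_freq <- n %/% 2 + 1
  freqs <- (0:(n_freq - 1)) * es$fs / n
  acc <- matrix(0, d[2], n_freq)
  for (e in seq_len(d[1])) {
    seg <- array(es$epochs[e, , , drop = FALSE], dim = d[2:3])
    for (j in seq_len(k)) {
      tx <- t(seg) * tap[, j]             # samples x channels, tapered
      X <- stats::mvfft(tx)[seq_len(n_freq), , drop = FALSE]
      acc <- acc + t(Mod(X)^2)
    }
  }
  pxx <- acc / (d[1] * k * es$fs)
  # one-sided: double all bins except DC and (if n even) Nyquist
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_freq] <- 1
  pxx <- sweep(pxx, 2, dbl, `*`)
  structure(list(freqs = freqs, power = pxx, n_epochs = d[1], fs = es$fs,
                 channels = es$channels),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d ch x %d freqs (0-%g Hz), %d epochs\n",
              nrow(x$power), length(x$freqs), max(x$freqs), x$n_epochs))
  invisible(x)
}

#' Band power from a PSD estimate
#'
#' Summarises the PSD over frequencies in `[f_lo, f_hi)`. The default is the
#' arithmetic mean of the density values in the band (muV^2/Hz); `"integral"`
#' integrates the density over the band instead (muV^2).
#'
#' @param psd A `psd_estimate`.
#' @param band A [band_spec()].
#' @param method `"mean"` (default) or `"integral"`.
#' @return Named numeric vector, one value per channel.
#' @export
band_power <- function(psd, band, method = c("mean", "integral")) {
  method <- match.arg(method)
  stopifnot(inherits(psd, "psd_estimate"), inherits(band, "band_spec"))
  if (band$f_hi > psd$fs / 2 + 1e-9) {
    stop("band ", band$name, " exceeds the spectral range (Nyquist ",
         psd$fs / 2, " Hz)")
  }
  sel <- psd$freqs >= band$f_lo & psd$freqs < band$f_hi
  if (!any(sel)) stop("band ", band$name, " contains no frequency bins")
  out <- if (method == "mean") {
    rowMeans(psd$power[, sel, drop = FALSE])
  } else {
    df <- psd$freqs[2] - psd$freqs[1]
    rowSums(psd$power[, sel, drop = FALSE]) * df
  }
  stats::setNames(out, psd$channels)
}

#' Band-power table for a set of subjects
#'
#' @param psds Named list of `psd_estimate`, one per subject.
#' @param bands List of [band_spec()] (default the five canonical bands).
#' @param groups Optional named vector of group labels per subject.
#' @param method Passed to [band_power()].
#' @return Long data frame: subject, group, channel, band, power.
#' @export
band_power_table <- function(psds, bands = eeg_bands(), groups = NULL,
                             method = "mean") {
  rows <- list()
  for (sid in names(psds)) {
    for (b in bands) {
      bp <- band_power(psds[[sid]], b, method)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid,
        group = if (is.null(groups)) NA_character_ else groups[[sid]],
        channel = names(bp), band = b$name, power = unname(bp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group band-power topography in decibels
#'
#' Per-channel group summary of band power: `10 * log10(power)` (dB re
#' 1 muV^2/Hz) averaged across the subjects of each group. Tabular output;
#' no scalp interpolation.
#'
#' @param bp_table Long table from [band_power_table()] (linear power).
#' @param band Band name to summarise.
#' @return Data frame: channel, group, mean_db.
#' @export
band_topography <- function(bp_table, band) {
  sub <- bp_table[bp_table$band == band, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for band '", band, "'")
  sub$db <- 10 * log10(sub$power)
  agg <- stats::aggregate(db ~ channel + group, data = sub, FUN = mean)
  names(agg)[names(agg) == "db"] <- "mean_db"
  agg[order(agg$group, match(agg$channel, MONTAGE_19)), ]
}
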