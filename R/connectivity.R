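# Weighted phase lag index (wPLI) connectivity. Per-epoch Hann-tapered FFT
# cross-spectra are pooled over epochs and in-band frequency bins, then the
# wPLI ratio |mean(Im S)| / mean(|Im S|) is formed per channel pair.

#' In-band cross-spectral terms for every channel pair
#'
#' For each epoch, channels are demeaned, Hann-tapered and Fourier
#' transformed; the complex cross-spectrum `X_i * Conj(X_j)` is collected at
#' every frequency bin inside `[f_lo, f_hi)`.
#'
#' @param es An [epoch_set()].
#' @param band A [band_spec()] inside the Nyquist range.
#' @return List with `pairs` (2-column matrix of channel indices, i < j) and
#'   `terms` (complex matrix, one row per pair, columns = epoch x bin
#'   samples), plus `channels`.
#' @export
band_cross_spectra <- function(es, band) {
  stopifnot(inherits(es, "epoch_set"), inherits(band, "band_spec"))
  d <- dim(es$epochs)
  n <- d[3]
  if (band$f_hi > es$fs / 2 + 1e-9) stop("band exceeds Nyquist")
  freqs <- (0:(n - 1)) * es$fs / n
  half <- seq_len(n %/% 2 + 1)
  sel <- which(freqs[half] >= band$f_lo & freqs[half] < band$f_hi &
                 freqs[half] > 0)
  if (!length(sel)) stop("band '", band$name, "' contains no frequency bins")
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hann
  pairs <- which(upper.tri(matrix(0, d[2], d[2])), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  terms <- matrix(complex(real = 0), nrow(pairs), d[1] * length(sel))
  col0 <- 0L
  for (e in seq_len(d[1])) {
    seg <- array(es$epochs[e, , , drop = FALSE], dim = d[2:3])
    seg <- seg - rowMeans(seg)
    X <- stats::mvfft(t(seg) * taper)[sel, , drop = FALSE]  # bins x channels
    cs <- X[, pairs[, 1], drop = FALSE] * Conj(X[, pairs[, 2], drop = FALSE])
    terms[, col0 + seq_along(sel)] <- t(cs)
    col0 <- col0 + length(sel)
  }
  list(pairs = pairs, terms = terms, channels = es$channels,
       n_epochs = d[1], band = band)
}

#' Weighted phase lag index from pooled cross-spectral terms
#'
#' `|mean(Im S)| / mean(|Im S|)` over all supplied terms. When every
#' imaginary part is zero (e.g. identical channels, zero-lag mixing only)
#' the value is defined as 0: no lagged relation is detectable.
#'
#' @param cross_terms Complex vector of cross-spectral values.
#' @return Scalar in `[0, 1]`.
#' @export
wpli <- function(cross_terms) {
  im <- Im(cross_terms)
  denom <- mean(abs(im))
  if (!length(im) || denom == 0) return(0)
  abs(mean(im)) / denom
}

#' Per-band wPLI connectivity matrix
#'
#' 19 x 19 (or n_channels squared) symmetric matrix of pairwise wPLI with a
#' zero diagonal, pooling cross-spectral terms across epochs and in-band
#' frequency bins.
#'
#' @param es An [epoch_set()].
#' @param band A [band_spec()].
#' @return Object of class `connectivity_matrix`: list with `values`
#'   (symmetric matrix), `band`, `n_epochs`, `channels`.
#' @export
connectivity_matrix <- function(es, band) {
  cs <- band_cross_spectra(es, band)
  n_ch <- length(cs$channels)
  m <- matrix(0, n_ch, n_ch, dimnames = list(cs$channels, cs$channels))
  for (p in seq_len(nrow(cs$pairs))) {
    v <- wpli(cs$terms[p, ])
    i <- cs$pairs[p, 1]; j <- cs$pairs[p, 2]
    m[i, j] <- v
    m[j, i] <- v
  }
  structure(list(values = m, band = band, n_epochs = cs$n_epochs,
                 channels = cs$channels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s band, %d channels, %d epochs, mean %.3f\n",
              x$band$name, length(x$channels), x$n_epochs,
              whole_brain_mean(x)))
  invisible(x)
}

#' Mean wPLI between (or within) scalp regions
#'
#' Mean over the unordered channel pairs with one endpoint in each region;
#' for `region_a == region_b` (intra-regional) the mean over the
#' `k * (k - 1) / 2` within-region pairs.
#'
#' @param cm A [connectivity_matrix()].
#' @param region_a,region_b Character vectors of channel labels, or names of
#'   entries of [region_partition()].
#' @return Scalar mean wPLI.
#' @export
region_mean <- function(cm, region_a, region_b = region_a) {
  rp <- region_partition()
  if (is.character(region_a) && length(region_a) == 1L &&
      region_a %in% names(rp)) region_a <- rp[[region_a]]
  if (is.character(region_b) && length(region_b) == 1L &&
      region_b %in% names(rp)) region_b <- rp[[region_b]]
  ia <- match(region_a, cm$channels)
  ib <- match(region_b, cm$channels)
  if (anyNA(ia) || anyNA(ib)) stop("region channel not in matrix")
  if (!length(ia) || !length(ib)) stop("empty region")
  if (setequal(ia, ib)) {
    if (length(ia) < 2) stop("intra-regional mean needs >= 2 channels")
    cmb <- t(utils::combn(sort(ia), 2))
    return(mean(cm$values[cmb]))
  }
  grid <- expand.grid(i = ia, j = ib)
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  lo <- pmin(grid$i, grid$j); hi <- pmax(grid$i, grid$j)
  keep <- !duplicated(paste(lo, hi))   # unordered pairs once, even if regions overlap
  mean(cm$values[cbind(lo, hi)][keep])
}

#' Whole-brain mean wPLI
#'
#' Mean of the `n(n-1)/2` upper-triangle entries (171 for 19 channels).
#'
#' @param cm A [connectivity_matrix()].
#' @return Scalar.
#' @export
whole_brain_mean <- function(cm) {
  mean(cm$values[upper.tri(cm$values)])
}

#' Long-format wPLI table across subjects and bands
#'
#' @param epoch_sets Named list of [epoch_set()] per subject.
#' @param bands List of [band_spec()].
#' @return Data frame: subject, group, band, chan_i, chan_j, wpli.
#' @export
wpli_table <- function(epoch_sets, bands = eeg_bands()) {
  rows <- list()
  for (sid in names(epoch_sets)) {
    es <- epoch_sets[[sid]]
    for (b in bands) {
      cm <- connectivity_matrix(es, b)
      ut <- which(upper.tri(cm$values), arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, group = es$group, band = b$name,
        chan_i = cm$channels[ut[, 1]], chan_j = cm$channels[ut[, 2]],
        wpli = cm$values[ut], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
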