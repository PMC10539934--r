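# Digital Butterworth design via the bilinear transform, factored into
# cascaded second-order sections (biquads) for numerical stability - a
# direct-form transfer function is unusable for cutoffs very close to DC
# (the 0.1 Hz high-pass at 200 Hz). Zero-phase filtering applies the cascade
# forwards then backwards with odd-reflection padding; checked in the tests
# against the analytic frequency response of the designed sections.

# Analog Butterworth prototype poles (unit cutoff, left half plane)
butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# bilinear transform of one analog section with poles `p` (length 1 or 2)
# and `nz` zeros at s = 0 (high-pass) or none (low-pass); returns b, a with
# unit gain at the reference frequency (DC for low-pass, Nyquist for high-pass)
.bilinear_section <- function(p, nz, fs, type) {
  fs2 <- 2 * fs
  zp <- (fs2 + p) / (fs2 - p)
  za <- if (type == "high") rep(1 + 0i, length(p)) else rep(-1 + 0i, length(p))
  poly_re <- function(r) {
    coef <- complex(real = 1)
    for (rt in r) coef <- c(coef, 0) - c(0, coef * rt)
    Re(coef)
  }
  b <- poly_re(za)
  a <- poly_re(zp)
  zref <- if (type == "low") 1 else -1
  g <- sum(a * zref^(seq_along(a) - 1)) / sum(b * zref^(seq_along(b) - 1))
  list(b = b * g, a = a)
}

#' Design a digital Butterworth filter
#'
#' Low-pass or high-pass Butterworth IIR filter via pole pre-warping and the
#' bilinear transform, returned as cascaded second-order sections (plus one
#' first-order section for odd orders).
#'
#' @param order Filter order (poles).
#' @param fc Cutoff frequency in Hz (-3 dB point).
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return Object of class `butter_filter`: list with `sections` (each a
#'   list with `b`, `a`), `order`, `fc`, `fs`, `type`.
#' @export
butter_design <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (!(fc > 0 && fc < fs / 2)) stop("invalid band edges: cutoff must lie in (0, fs/2)")
  wc <- 2 * fs * tan(pi * fc / fs)          # pre-warped analog cutoff (rad/s)
  proto <- butter_prototype(order)
  poles <- if (type == "low") wc * proto else wc / proto
  # pair conjugate poles into biquads; a lone real pole makes a 1st-order section
  used <- rep(FALSE, order)
  sections <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    p <- poles[i]
    if (abs(Im(p)) < 1e-9 * abs(p)) {
      used[i] <- TRUE
      pair <- Re(p)
    } else {
      j <- which(!used & abs(poles - Conj(p)) < 1e-6 * abs(p))
      j <- setdiff(j, i)[1]
      used[c(i, j)] <- TRUE
      pair <- c(p, Conj(p))
    }
    sections[[length(sections) + 1L]] <-
      .bilinear_section(pair, length(pair), fs, type)
  }
  structure(list(sections = sections, order = order, fc = fc, fs = fs,
                 type = type),
            class = "butter_filter")
}

#' Frequency response of a designed filter
#'
#' Evaluates `H(e^{i 2 pi f / fs})` as the product over the filter's
#' second-order sections (or for a plain `list(b, a)` transfer function).
#'
#' @param filt A `butter_filter` from [butter_design()], or a list with
#'   `b` and `a`.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz).
#' @return Complex response, same length as `f`.
#' @export
freq_response <- function(filt, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  eval_tf <- function(b, a) {
    num <- 0i; den <- 0i
    for (k in seq_along(b)) num <- num + b[k] * z1^(k - 1)
    for (k in seq_along(a)) den <- den + a[k] * z1^(k - 1)
    num / den
  }
  if (inherits(filt, "butter_filter")) {
    h <- complex(real = rep(1, length(f)))
    for (s in filt$sections) h <- h * eval_tf(s$b, s$a)
    h
  } else {
    eval_tf(filt$b, filt$a)
  }
}

# single-pass filter of one section, started in the steady state for a
# constant input x[1] (removes the DC start-up transient; the oscillatory
# residue is absorbed by the reflection padding of filtfilt_zp)
.filter_section <- function(b, a, x) {
  x0 <- x[1]
  v <- stats::filter(c(rep(x0, length(b) - 1), x), b, method = "convolution",
                     sides = 1)
  v <- v[-seq_len(length(b) - 1)]
  if (length(a) > 1) {
    h1 <- sum(b) / sum(a)
    v <- stats::filter(v, -a[-1], method = "recursive",
                       init = rep(x0 * h1, length(a) - 1))
  }
  as.numeric(v)
}

# forward pass through the full cascade
iir_filter <- function(filt, x) {
  if (inherits(filt, "butter_filter")) {
    for (s in filt$sections) x <- .filter_section(s$b, s$a, x)
    x
  } else {
    .filter_section(filt$b, filt$a, x)
  }
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter cascade forwards then backwards, squaring the
#' magnitude response and cancelling phase distortion. The signal is
#' extended at both ends by odd reflection to suppress start-up transients
#' (generous padding, because zero initial conditions are used).
#'
#' @param filt A `butter_filter` (or `list(b, a)`).
#' @param x Numeric vector.
#' @param pad_len Reflection padding length; default `min(length(x) - 1,
#'   1000)`.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_zp <- function(filt, x, pad_len = NULL) {
  n <- length(x)
  if (is.null(pad_len)) pad_len <- min(n - 1, 1000)
  if (pad_len > 0) {
    pre <- 2 * x[1] - x[(pad_len + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad_len)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- iir_filter(filt, ext)
  y <- rev(iir_filter(filt, rev(y)))
  y[(pad_len + 1):(pad_len + n)]
}
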