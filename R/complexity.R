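#' Coarse-grain a time series
#'
#' Non-overlapping window means at scale `tau`: element `j` of the output is
#' the mean of `x[(j-1)*tau + 1 .. j*tau]`; a trailing partial window is
#' dropped, so the output has length `floor(length(x)/tau)`.
#'
#' @param x Numeric vector.
#' @param tau Integer scale factor >= 1.
#' @return Numeric vector of length `floor(length(x)/tau)`.
#' @export
coarse_grain <- function(x, tau) {
  if (!(is.numeric(tau) && length(tau) == 1L && tau >= 1 &&
        tau == round(tau))) {
    stop("tau must be an integer >= 1")
  }
  tau <- as.integer(tau)
  if (length(x) < tau) stop("series shorter than one window")
  if (tau == 1L) return(as.numeric(x))
  n <- (length(x) %/% tau) * tau
  colMeans(matrix(x[seq_len(n)], nrow = tau))
}

#' Sample entropy
#'
#' Negative natural logarithm of the conditional probability that templates
#' matching for `m` points (Chebyshev distance within the tolerance) still
#' match at point `m + 1`. Self-matches are excluded; the tolerance is
#' `r * sd(y)` (SD-relative convention). Returns 0 for a constant series and
#' `NaN` when no template pair matches at length `m + 1` (undefined).
#'
#' @param y Numeric vector, length > `m + 1`.
#' @param m Embedding dimension (default 1).
#' @param r Tolerance as a fraction of the series SD (default 0.25).
#' @param r_absolute Optional absolute tolerance overriding `r * sd(y)`.
#' @return Scalar entropy in nats.
#' @export
sample_entropy <- function(y, m = 1L, r = 0.25, r_absolute = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n <= m + 1L) stop("series too short for embedding dimension m = ", m)
  if (is.null(r_absolute)) {
    if (r <= 0) stop("r must be > 0")
    sdy <- stats::sd(y)
    if (sdy == 0) return(0)  # constant series: all templates match at m and m+1
    r_absolute <- r * sdy
  }
  cnt <- .sampen_counts(y, as.integer(m), r_absolute)
  B <- cnt[1]; A <- cnt[2]
  if (B == 0) return(NaN)
  if (A == 0) return(NaN)
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy (bits) of the distribution of ordinal patterns of length
#' `m` over all `length(y) - m + 1` sliding windows, with relative
#' frequencies `f(motif)/(N - m + 1)`. Ties are broken by order of
#' appearance (stable sort). Bounded by `log2(factorial(m))`.
#'
#' @param y Numeric vector, `length(y) >= m`.
#' @param m Motif length (default 3).
#' @return Scalar entropy in bits.
#' @export
permutation_entropy <- function(y, m = 3L) {
  y <- as.numeric(y)
  n <- length(y)
  m <- as.integer(m)
  if (n < m) stop("series shorter than motif length m = ", m)
  n_win <- n - m + 1L
  win <- matrix(NA_real_, n_win, m)
  for (k in seq_len(m)) win[, k] <- y[k:(n - m + k)]
  codes <- apply(win, 1L, function(v)
    paste(order(v), collapse = ""))  # order() breaks ties by appearance
  p <- tabulate(factor(codes)) / n_win
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Multiscale entropy curve
#'
#' Entropy of the coarse-grained series at each scale factor, for sample
#' entropy or permutation entropy. With `r_mode = "scale"` (default) the
#' sample-entropy tolerance is `r * sd` of the coarse-grained series at each
#' scale; `r_mode = "original"` fixes it to `r * sd(x)` of the original
#' series (the classic multiscale-entropy convention, under which white
#' noise gives a decreasing curve).
#'
#' @param x Numeric vector (typically a channel's concatenated epochs).
#' @param estimator `"sample"` or `"permutation"`.
#' @param scales Integer vector of scale factors (default `1:30`).
#' @param m Embedding dimension / motif length (defaults: 1 for sample
#'   entropy, 3 for permutation entropy).
#' @param r Sample-entropy tolerance fraction (default 0.25).
#' @param r_mode `"scale"` or `"original"` (sample entropy only).
#' @return Object of class `multiscale_curve`: data frame with `scale`,
#'   `value`, plus attributes `estimator` and `params`.
#' @export
multiscale_curve <- function(x, estimator = c("sample", "permutation"),
                             scales = 1:30, m = NULL, r = 0.25,
                             r_mode = c("scale", "original")) {
  estimator <- match.arg(estimator)
  r_mode <- match.arg(r_mode)
  if (is.null(m)) m <- if (estimator == "sample") 1L else 3L
  need <- if (estimator == "sample") m + 2L else m
  if (length(x) / max(scales) < need) {
    stop("series too short (", length(x), ") for scale ", max(scales))
  }
  r_abs <- if (estimator == "sample" && r_mode == "original") {
    r * stats::sd(x)
  } else NULL
  vals <- vapply(scales, function(tau) {
    y <- coarse_grain(x, tau)
    if (estimator == "sample") {
      sample_entropy(y, m = m, r = r, r_absolute = r_abs)
    } else {
      permutation_entropy(y, m = m)
    }
  }, numeric(1))
  structure(data.frame(scale = as.integer(scales), value = vals),
            estimator = estimator,
            params = list(m = m, r = r, r_mode = r_mode),
            class = c("multiscale_curve", "data.frame"))
}

#' Multiscale entropy table for an epoch set
#'
#' Computes per-channel multiscale curves on the concatenated selected
#' epochs of each channel.
#'
#' @param es An [epoch_set()].
#' @param estimator,scales,m,r,r_mode Passed to [multiscale_curve()].
#' @return Long data frame: subject, group, channel, estimator, scale, value.
#' @export
entropy_table <- function(es, estimator = "sample", scales = 1:30,
                          m = NULL, r = 0.25, r_mode = "scale") {
  rows <- lapply(es$channels, function(ch) {
    x <- concat_channel(es, ch)
    mc <- multiscale_curve(x, estimator, scales, m = m, r = r,
                           r_mode = r_mode)
    data.frame(subject = es$subject_id, group = es$group, channel = ch,
               estimator = estimator, scale = mc$scale, value = mc$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
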