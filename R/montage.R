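#' The 19-channel international 10-20 montage
#'
#' Channel labels, canonical frequency bands, and the scalp-region partition
#' used throughout the package.
#'
#' @format `MONTAGE_19` is a character vector of the 19 electrode labels in
#'   canonical order.
#' @export
MONTAGE_19 <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8",
                "C3", "C4", "T3", "T4", "T5", "T6",
                "P3", "P4", "O1", "O2", "Cz", "Fz", "Pz")

#' Canonical EEG frequency bands
#'
#' The five bands used for spectral, connectivity and graph analyses:
#' delta (0.1-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), beta (12-30 Hz) and
#' gamma (30-45 Hz).
#'
#' @param name Band name, one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`, or `NULL` to return all five as a named list.
#' @return A `band_spec` (list with `name`, `f_lo`, `f_hi`), or a named list
#'   of all five.
#' @export
#' @examples
#' eeg_bands("theta")$f_lo  # 4
eeg_bands <- function(name = NULL) {
  bands <- list(
    delta = band_spec("delta", 0.1, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 12, 30),
    gamma = band_spec("gamma", 30, 45)
  )
  if (is.null(name)) return(bands)
  if (!name %in% names(bands)) {
    stop("unknown band '", name, "'; expected one of ",
         paste(names(bands), collapse = ", "))
  }
  bands[[name]]
}

#' Construct a frequency band specification
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo >= 0 && f_lo < f_hi)) {
    stop("invalid band edges: need 0 <= f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Scalp region partition
#'
#' Frontal, central (centro-temporal) and parieto-occipital electrode groups.
#' The three regions are disjoint and their union is the full 19-channel
#' montage.
#'
#' @return Named list of character vectors `frontal`, `central`,
#'   `parieto_occipital`.
#' @export
region_partition <- function() {
  list(
    frontal = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
    central = c("C3", "C4", "T3", "T4", "Cz"),
    parieto_occipital = c("P3", "P4", "O1", "O2", "T5", "T6", "Pz")
  )
}

check_channels <- function(channels) {
  bad <- setdiff(channels, MONTAGE_19)
  if (length(bad)) {
    stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  invisible(TRUE)
}
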