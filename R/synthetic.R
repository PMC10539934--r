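# Synthetic two-group EEG cohorts with known ground truth. Band-limited
# oscillations are synthesised as Butterworth-filtered white noise;
# phase-lagged coupling shares a source between two channels with one copy
# delayed; volume conduction is instantaneous linear mixing; the MCI-like
# "entropy deficit" raises the AR(1) coefficient of target channels' noise.

#' Specification of a synthetic two-group cohort
#'
#' Defaults encode the study-like "stated world": 13 healthy controls vs 12
#' MCI subjects, 19-channel 10-20 montage at 200 Hz, 104 s per subject
#' (52 two-second epochs, of which 50 are selected), band-limited background
#' oscillations in the five canonical bands, a long-range theta coupling
#' scaffold in the HC group versus weaker, within-region theta coupling in
#' the MCI group (connectivity deficit with elevated local clustering), a
#' mid-temporal (C3/C4) regularity increase in the MCI group (entropy
#' deficit), and mild zero-lag mixing on all channels.
#'
#' @param n_hc,n_mci Subject counts (each >= 2).
#' @param fs Sampling rate in Hz (> twice the highest band edge).
#' @param duration Seconds per subject.
#' @param band_amplitudes Named list `HC`/`MCI`, each a named numeric vector
#'   of per-band oscillation SD in muV.
#' @param coupling_edges Data frame with columns `group`, `chan_i`, `chan_j`,
#'   `band`, `lag` (radians), `strength` (muV SD of the shared source).
#' @param mixing_leakage Zero-lag cross-channel mixing coefficient in
#'   `[0, 1)`.
#' @param noise_sd Broadband per-channel noise SD in muV.
#' @param entropy_deficit_channels Channels whose MCI-group noise is made
#'   more regular.
#' @param entropy_deficit_ar AR(1) coefficient applied to those channels in
#'   the MCI group (HC noise is white).
#' @param seed Integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 13L, n_mci = 12L, fs = 200, duration = 104,
                        band_amplitudes = default_band_amplitudes(),
                        coupling_edges = default_coupling_edges(),
                        mixing_leakage = 0.05, noise_sd = 3,
                        entropy_deficit_channels = c("C3", "C4"),
                        entropy_deficit_ar = 0.95, seed = 42L) {
  if (n_hc < 2 || n_mci < 2) stop("each group needs >= 2 subjects")
  f_max <- max(vapply(eeg_bands(), function(b) b$f_hi, numeric(1)))
  if (fs <= 2 * f_max) stop("fs must exceed twice the highest band edge (",
                            2 * f_max, " Hz)")
  if (!(mixing_leakage >= 0 && mixing_leakage < 1)) {
    stop("mixing_leakage must lie in [0, 1)")
  }
  stopifnot(is.data.frame(coupling_edges),
            all(c("group", "chan_i", "chan_j", "band", "lag", "strength")
                %in% names(coupling_edges)))
  check_channels(unique(c(coupling_edges$chan_i, coupling_edges$chan_j)))
  check_channels(entropy_deficit_channels)
  stopifnot(all(coupling_edges$band %in% names(eeg_bands())))
  structure(
    list(n_hc = as.integer(n_hc), n_mci = as.integer(n_mci), fs = fs,
         duration = duration, band_amplitudes = band_amplitudes,
         coupling_edges = coupling_edges, mixing_leakage = mixing_leakage,
         noise_sd = noise_sd,
         entropy_deficit_channels = entropy_deficit_channels,
         entropy_deficit_ar = entropy_deficit_ar, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> HC n=%d, MCI n=%d, %g Hz, %g s, %d coupling edges, seed %d\n",
    x$n_hc, x$n_mci, x$fs, x$duration, nrow(x$coupling_edges), x$seed))
  invisible(x)
}

#' Default per-band background amplitudes (muV SD)
#'
#' Identical for both groups: the default group differences live in the
#' coupling structure and the entropy deficit, not in band power.
#'
#' @return Named list with `HC` and `MCI` numeric vectors.
#' @export
default_band_amplitudes <- function() {
  amps <- c(delta = 8, theta = 3, alpha = 7, beta = 3, gamma = 1.5)
  list(HC = amps, MCI = amps)
}

#' Default ground-truth coupling edges
#'
#' HC: two shared theta sources, one over the left hemisphere plus midline
#' and one over the right (bridged through Pz), each driving seven channels
#' at staggered lags - an integrative whole-scalp scaffold of lagged
#' coupling, yielding high theta global efficiency once binarised. MCI: a
#' single shared theta source confined to the seven frontal channels at
#' reduced strength - a theta coupling deficit whose reliable connections
#' form one local clique (elevated clustering, markedly lower global
#' efficiency at sparsity thresholds near the true edge count). Lags are
#' staggered in steps of 0.1 pi so every within-source channel pair has a
#' constant nonzero phase difference well away from 0 and pi.
#'
#' @param hc_strength,mci_strength Source SD in muV for each group's edges.
#' @return Data frame of coupling rows (columns `group`, `chan_i`, `chan_j`,
#'   `band`, `lag`, `strength`, `source`).
#' @export
default_coupling_edges <- function(hc_strength = 5, mci_strength = 4) {
  star <- function(group, source, hub, members, strength) {
    # lags spaced so every pairwise phase difference stays in
    # [0.14 pi, 0.85 pi]: well away from 0 and pi, where the imaginary
    # cross-spectrum (and hence wPLI) vanishes
    data.frame(group = group, chan_i = hub, chan_j = members,
               band = "theta",
               lag = seq(0.15 * pi, 0.85 * pi, length.out = length(members)),
               strength = strength, source = source,
               stringsAsFactors = FALSE)
  }
  rbind(
    star("HC", "hc_left", "Fz",
         c("Pz", "C3", "P3", "O1", "T5", "Fp1"), hc_strength),
    star("HC", "hc_right", "Pz",
         c("C4", "P4", "O2", "T6", "Fp2", "T4"), hc_strength),
    star("MCI", "mci_frontal", "Fz",
         c("Fp1", "Fp2", "F3", "F4", "F7", "F8"), mci_strength))
}

# Spatial weighting of background band amplitude: frontal delta dominance,
# occipital theta/alpha dominance - the canonical resting-state topography.
.band_spatial_weight <- function(band) {
  w <- stats::setNames(rep(1, length(MONTAGE_19)), MONTAGE_19)
  if (band == "delta") w[c("Fp1", "Fp2")] <- 2
  if (band == "theta") w[c("O1", "O2")] <- 1.5
  if (band == "alpha") {
    w[c("O1", "O2")] <- 2
    w[c("P3", "P4", "Pz")] <- 1.5
  }
  w
}

# Band-limited unit-SD noise: white noise shaped in the frequency domain by
# the squared magnitude response of the zero-phase 4th-order Butterworth
# band-pass cascade (identical spectral shaping to forward-backward
# filtering, with circular boundary - irrelevant for noise synthesis).
# Columns are independent series.
.band_noise_gain <- local({
  cache <- new.env(parent = emptyenv())
  function(n, band, fs) {
    key <- paste(n, band$name, band$f_lo, band$f_hi, fs, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- (0:(n - 1)) * fs / n
    f <- pmin(f, fs - f)                   # two-sided grid folded to [0, fs/2]
    lp <- butter_design(4L, band$f_hi, fs, "low")
    g <- Mod(freq_response(lp, f, fs))^2
    if (band$f_lo > 0) {
      hp <- butter_design(4L, band$f_lo, fs, "high")
      g <- g * Mod(freq_response(hp, f, fs))^2
    }
    cache[[key]] <- g
    g
  }
})

.band_noise <- function(n, band, fs, k = 1L) {
  x <- matrix(stats::rnorm(n * k), n, k)
  g <- .band_noise_gain(n, band, fs)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n
  y <- sweep(y, 2, apply(y, 2, stats::sd), `/`)
  if (k == 1L) y[, 1] else y
}

#' Generate one synthetic subject
#'
#' Reproducible given `(spec$seed, group, subject_index)`. See
#' [cohort_spec()] for the signal model.
#'
#' @param spec A [cohort_spec()].
#' @param group `"HC"` or `"MCI"`.
#' @param subject_index Integer index within the group.
#' @return An [eeg_recording()].
#' @export
generate_subject <- function(spec, group, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("HC", "MCI")) stop("group must be 'HC' or 'MCI'")
  if (spec$duration < 2) stop("duration shorter than one epoch")
  n <- round(spec$duration * spec$fs)
  n_ch <- length(MONTAGE_19)
  subj_seed <- spec$seed + 100003L * (group == "MCI") + 211L * as.integer(subject_index)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(subj_seed %% .Machine$integer.max)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  amps <- spec$band_amplitudes[[group]]
  x <- matrix(0, n_ch, n, dimnames = list(MONTAGE_19, NULL))

  # background band-limited oscillations, independent per channel
  for (bn in names(amps)) {
    if (amps[[bn]] <= 0) next
    b <- eeg_bands(bn)
    w <- .band_spatial_weight(bn)
    bg <- .band_noise(n, b, spec$fs, k = n_ch)
    x <- x + t(bg) * (amps[[bn]] * w)
  }

  # constant phase-lag coupling: a shared band-limited source per edge (or
  # per `source` id, when several rows name the same source), added to
  # chan_i undelayed and to chan_j delayed by lag/(2 pi f_center) seconds.
  # Within a source group each channel receives the source once, at the
  # first delay assigned to it, so a lagged clique can be written as a star.
  edges <- spec$coupling_edges[spec$coupling_edges$group == group, ,
                               drop = FALSE]
  if (nrow(edges)) {
    src_id <- if ("source" %in% names(edges)) edges$source else
      rep(NA_character_, nrow(edges))
    src_id[is.na(src_id)] <- paste0(".row", which(is.na(src_id)))
    for (sid in unique(src_id)) {
      rows <- edges[src_id == sid, , drop = FALSE]
      b <- eeg_bands(rows$band[1])
      f_c <- (b$f_lo + b$f_hi) / 2
      delays <- integer(0)     # channel index -> delay in samples
      strengths <- numeric(0)
      for (k in seq_len(nrow(rows))) {
        e <- rows[k, ]
        if (e$strength <= 0) next
        i <- as.character(match(e$chan_i, MONTAGE_19))
        j <- as.character(match(e$chan_j, MONTAGE_19))
        dj <- round(e$lag / (2 * pi * f_c) * spec$fs)
        if (is.na(delays[i])) { delays[i] <- 0L; strengths[i] <- e$strength }
        if (is.na(delays[j])) { delays[j] <- dj; strengths[j] <- e$strength }
      }
      if (!length(delays)) next
      dmax <- max(abs(delays))
      src <- .band_noise(n + 2 * dmax, b, spec$fs)
      for (ch in names(delays)) {
        off <- dmax - delays[[ch]]
        x[as.integer(ch), ] <- x[as.integer(ch), ] +
          strengths[[ch]] * src[(off + 1):(off + n)]
      }
    }
  }

  # broadband noise; AR(1) regularisation on entropy-deficit channels (MCI)
  deficit <- group == "MCI" & MONTAGE_19 %in% spec$entropy_deficit_channels
  for (ch in seq_len(n_ch)) {
    eps <- stats::rnorm(n)
    if (deficit[ch] && spec$entropy_deficit_ar > 0) {
      phi <- spec$entropy_deficit_ar
      z <- as.numeric(stats::filter(eps, phi, method = "recursive"))
      z <- z * sqrt(1 - phi^2)             # unit marginal SD
    } else {
      z <- eps
    }
    x[ch, ] <- x[ch, ] + spec$noise_sd * z
  }

  # zero-lag volume-conduction mixing: identity + leakage on every off-diagonal
  if (spec$mixing_leakage > 0) {
    M <- matrix(spec$mixing_leakage, n_ch, n_ch)
    diag(M) <- 1
    x <- M %*% x
  }

  eeg_recording(x, spec$fs,
                subject_id = sprintf("%s%02d", tolower(group), subject_index),
                group = group)
}

#' Generate a full two-group cohort
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (named list of [eeg_recording()]) and
#'   `groups` (named character vector of group labels per subject).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  for (i in seq_len(spec$n_hc)) {
    r <- generate_subject(spec, "HC", i)
    recs[[r$subject_id]] <- r
  }
  for (i in seq_len(spec$n_mci)) {
    r <- generate_subject(spec, "MCI", i)
    recs[[r$subject_id]] <- r
  }
  groups <- vapply(recs, function(r) r$group, character(1))
  list(recordings = recs, groups = groups)
}

#' Read a cohort specification from a JSON file
#'
#' All fields of [cohort_spec()] may be supplied; missing fields take the
#' defaults. `coupling_edges` is given as a data-frame-like JSON array of
#' objects.
#'
#' @param path Path to a JSON file.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("n_hc", "n_mci", "fs", "duration", "mixing_leakage",
              "noise_sd", "entropy_deficit_channels", "entropy_deficit_ar",
              "seed")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$band_amplitudes)) {
    args$band_amplitudes <- lapply(cfg$band_amplitudes, unlist)
  }
  if (!is.null(cfg$coupling_edges)) {
    args$coupling_edges <- as.data.frame(cfg$coupling_edges)
  }
  do.call(cohort_spec, args)
}
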