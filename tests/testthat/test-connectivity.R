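test_that("cross-spectra have the expected phase structure", {
  fs <- 200
  t <- (0:(10 * 400 - 1)) / fs
  phi <- pi / 3
  m <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t - phi))
  es <- es_from_matrix(m, fs, channels = c("C3", "C4"))
  cs <- band_cross_spectra(es, eeg_bands("alpha"))
  # phase of the pooled cross-spectrum at the peak bin ~ phi
  ph <- Arg(mean(cs$terms[1, ]))
  expect_equal(ph, phi, tolerance = 0.05)
  # identical channels: purely real cross-spectrum
  es2 <- es_from_matrix(rbind(m[1, ], m[1, ]), fs, channels = c("C3", "C4"))
  cs2 <- band_cross_spectra(es2, eeg_bands("alpha"))
  expect_lt(max(abs(Im(cs2$terms))), 1e-8 * max(Mod(cs2$terms)))
  # zero signals: zero cross-spectrum
  es3 <- es_from_matrix(matrix(0, 2, 4000), fs, channels = c("C3", "C4"))
  expect_true(all(Mod(band_cross_spectra(es3, eeg_bands("alpha"))$terms) == 0))
})

test_that("wpli matches its defining ratio and limiting values", {
  expect_equal(wpli(complex(real = rnorm(50), imaginary = abs(rnorm(50)))), 1)
  expect_equal(wpli(complex(real = rnorm(50),
                            imaginary = c(rep(2, 25), rep(-2, 25)))), 0)
  expect_identical(wpli(complex(real = rnorm(5), imaginary = rep(0, 5))), 0)
  set.seed(33)
  for (rep in 1:10) {
    z <- complex(real = rnorm(200), imaginary = rnorm(200))
    expect_equal(wpli(z), oracle_wpli(z), tolerance = 1e-12)
  }
})

test_that("connectivity matrix is symmetric with zero diagonal and finds injected coupling", {
  edges <- data.frame(group = "HC", chan_i = "C3", chan_j = "P3",
                      band = "theta", lag = pi / 2, strength = 12,
                      stringsAsFactors = FALSE)
  amps <- list(HC = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
               MCI = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0))
  sp <- cohort_spec(band_amplitudes = amps, coupling_edges = edges,
                    mixing_leakage = 0, noise_sd = 1,
                    entropy_deficit_ar = 0, duration = 104, seed = 9)
  es <- preprocess_subject(generate_subject(sp, "HC", 1))
  cm <- connectivity_matrix(es, eeg_bands("theta"))
  expect_identical(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 0))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  # the injected pair is the matrix maximum and near 1
  expect_gt(cm$values["C3", "P3"], 0.8)
  expect_equal(max(cm$values), cm$values["C3", "P3"])
})

test_that("no phase coupling means wPLI at the noise floor", {
  amps <- list(HC = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
               MCI = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0))
  none <- default_coupling_edges()[0, ]
  sp <- cohort_spec(band_amplitudes = amps, coupling_edges = none,
                    mixing_leakage = 0, noise_sd = 1,
                    entropy_deficit_ar = 0, duration = 104, seed = 5)
  es <- preprocess_subject(generate_subject(sp, "HC", 1))
  cm <- connectivity_matrix(es, eeg_bands("theta"))
  expect_lt(whole_brain_mean(cm), 0.15)
})

test_that("zero-lag mixing creates amplitude correlation but no wPLI", {
  amps <- list(HC = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
               MCI = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0))
  none <- default_coupling_edges()[0, ]
  mixed <- cohort_spec(band_amplitudes = amps, coupling_edges = none,
                       mixing_leakage = 0.4, noise_sd = 1,
                       entropy_deficit_ar = 0, duration = 104, seed = 6)
  unmixed <- cohort_spec(band_amplitudes = amps, coupling_edges = none,
                         mixing_leakage = 0, noise_sd = 1,
                         entropy_deficit_ar = 0, duration = 104, seed = 6)
  rec_m <- generate_subject(mixed, "HC", 1)
  rec_u <- generate_subject(unmixed, "HC", 1)
  # mixing produces strong instantaneous correlation ...
  expect_gt(cor(rec_m$data[1, ], rec_m$data[2, ]), 0.5)
  expect_lt(abs(cor(rec_u$data[1, ], rec_u$data[2, ])), 0.1)
  # ... but leaves the mean wPLI at (or below) the unmixed noise floor
  cm_m <- connectivity_matrix(preprocess_subject(rec_m), eeg_bands("theta"))
  cm_u <- connectivity_matrix(preprocess_subject(rec_u), eeg_bands("theta"))
  expect_lt(whole_brain_mean(cm_m), 0.15)
  expect_lt(whole_brain_mean(cm_m), whole_brain_mean(cm_u) + 0.02)
})

test_that("wPLI noise floor decreases with epoch count", {
  amps <- list(HC = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
               MCI = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0))
  none <- default_coupling_edges()[0, ]
  floors <- vapply(c(10, 30, 50), function(ne) {
    vals <- vapply(1:3, function(s) {
      sp <- cohort_spec(band_amplitudes = amps, coupling_edges = none,
                        mixing_leakage = 0, noise_sd = 1,
                        entropy_deficit_ar = 0,
                        duration = 2 * ne + 4, seed = 100 + s)
      es <- preprocess_subject(generate_subject(sp, "HC", 1), n_keep = ne)
      whole_brain_mean(connectivity_matrix(es, eeg_bands("theta")))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(floors) < 0))
})

test_that("region means average exactly the right pairs", {
  set.seed(40)
  w <- matrix(runif(19 * 19), 19, 19)
  w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(MONTAGE_19, MONTAGE_19)
  cm <- structure(list(values = w, band = eeg_bands("theta"),
                       n_epochs = 50, channels = MONTAGE_19),
                  class = "connectivity_matrix")
  rp <- region_partition()
  # intra-frontal: 21 pairs
  fr <- rp$frontal
  manual <- mean(w[t(combn(match(fr, MONTAGE_19), 2))])
  expect_equal(region_mean(cm, "frontal"), manual, tolerance = 1e-12)
  # inter frontal-central: 7 x 5 pairs
  ce <- rp$central
  vals <- c()
  for (i in match(fr, MONTAGE_19)) for (j in match(ce, MONTAGE_19)) {
    vals <- c(vals, w[min(i, j), max(i, j)])
  }
  expect_equal(region_mean(cm, "frontal", "central"), mean(vals),
               tolerance = 1e-12)
  # constant matrix: every region mean equals the constant
  wc <- matrix(0.3, 19, 19); diag(wc) <- 0
  dimnames(wc) <- list(MONTAGE_19, MONTAGE_19)
  cmc <- structure(list(values = wc, band = eeg_bands("theta"),
                        n_epochs = 50, channels = MONTAGE_19),
                   class = "connectivity_matrix")
  expect_equal(region_mean(cmc, "frontal"), 0.3)
  expect_equal(region_mean(cmc, "central", "parieto_occipital"), 0.3)
  # whole-brain mean equals the upper-triangle mean
  expect_equal(whole_brain_mean(cm), mean(w[upper.tri(w)]), tolerance = 1e-12)
  # regions partition the montage
  expect_identical(sort(unlist(rp, use.names = FALSE)), sort(MONTAGE_19))
})

test_that("channel permutation permutes the matrix consistently", {
  fs <- 200
  set.seed(41)
  m <- matrix(rnorm(4 * 4000), 4)
  chans <- c("Fp1", "C3", "P3", "O1")
  es <- es_from_matrix(m, fs, channels = chans)
  cm <- connectivity_matrix(es, eeg_bands("alpha"))
  perm <- c(3, 1, 4, 2)
  es2 <- es_from_matrix(m[perm, ], fs, channels = chans[perm])
  cm2 <- connectivity_matrix(es2, eeg_bands("alpha"))
  expect_equal(cm2$values[chans, chans], cm$values[chans, chans],
               tolerance = 1e-12)
})
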