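# EEG feature pipeline: preprocessing filters, band powers, frontal
# band-power features, hemispheric asymmetry, inter-subject correlations,
# and the rank transform.

test_that("re-referencing zeroes Cz and DC input is removed by the high-pass", {
  n <- 2000
  dat <- matrix(5, 8, n)   # pure DC on every channel
  tr <- make_tone_trial(n = n)
  tr$data[] <- dat
  out <- preprocess_eeg(tr)
  expect_true(all(out$data["Cz", ] == 0))
  trim <- 300
  core <- out$data[, (trim + 1):(n - trim)]
  expect_lt(max(abs(core)), 1e-6 * 5)
})

test_that("the 50 Hz notch attenuates a 50 Hz tone by more than 10x", {
  tr <- make_tone_trial(list(Fp1 = tone(50, 1)), n = 3000)
  out <- preprocess_eeg(tr)
  core <- 501:2500
  rms_in <- sqrt(mean(tr$data["Fp1", core]^2))
  rms_out <- sqrt(mean(out$data["Fp1", core]^2))
  expect_lt(rms_out, 0.1 * rms_in)
})

test_that("a 10 Hz tone lands in the alpha band of the spectrogram", {
  tr <- make_tone_trial(list(Fp1 = tone(10, 1)), n = 1500)
  bands <- eeg_bands()$band
  bp <- sapply(bands, function(b) band_power_series(tr, "Fp1", b))
  alpha <- bp[, "alpha"]
  for (b in setdiff(bands, "alpha"))
    expect_true(all(alpha > 20 * bp[, b]))
  expect_true(all(bp >= 0))
  expect_equal(nrow(bp), 1500 - 1000 + 1)
})

test_that("equal-amplitude well-separated tones give near-equal band powers", {
  # 6 Hz sits in theta (4-7.5 Hz), 30 Hz in gamma (26-40 Hz)
  tr <- make_tone_trial(list(Fp1 = rbind(tone(6, 1), tone(30, 1))), n = 2000)
  theta <- mean(band_power_series(tr, "Fp1", "theta"))
  gamma <- mean(band_power_series(tr, "Fp1", "gamma"))
  expect_lt(abs(theta - gamma) / max(theta, gamma), 0.1)
})

test_that("near-zero signal yields the log-floor features", {
  tr <- make_tone_trial(n = 1200)   # noise at the 1e-9 fixture floor
  f <- fbp_features(tr)
  expect_length(f, 15)
  expect_true(all(f < -11.5))       # ~ log10(1e-12)
})

test_that("band powers are non-negative and bands never exceed total power", {
  set.seed(7)
  tr <- make_tone_trial(list(Fp1 = rbind(tone(3, 1), tone(10, 0.5), tone(33, 0.2))),
                        n = 1400, noise_sd = 0.3)
  e <- graphsrc:::stft_band_energies(tr$data["Fp1", ], tr$rate)
  expect_true(all(e >= 0))
  # total spectral power per window (all bins, both sides)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:999) / 1000)
  x <- tr$data["Fp1", ]
  total <- sapply(seq_len(ncol(e)), function(s)
    sum(Mod(fft(x[s:(s + 999)] * win))^2))
  expect_true(all(colSums(e) <= total + 1e-8))
})

test_that("fbp picks out a tone on the right channel and band", {
  tr <- make_tone_trial(list(Fp1 = tone(10, 1)), n = 1500)
  f <- fbp_features(tr)
  expect_equal(names(which.max(f)), "fbp_Fp1_alpha")
})

test_that("asymmetry is zero for identical hemispheres and log10(4) for 2x amplitude", {
  tr <- make_tone_trial(list(F7 = tone(10, 1), F8 = tone(10, 1)), n = 1500)
  tr$data["F8", ] <- tr$data["F7", ]
  a <- asymmetry_features(tr)
  expect_length(a, 5)
  expect_equal(unname(a), rep(0, 5))

  # doubled amplitude: power scales with amplitude^2, so the log10 difference is log10(4)
  tr2 <- make_tone_trial(list(F7 = tone(10, 2), F8 = tone(10, 1)), n = 2500)
  a2 <- asymmetry_features(tr2)
  expect_equal(unname(a2["asym_alpha"]), log10(4), tolerance = 0.05 * log10(4))
})

test_that("fbp and asymmetry ignore a DC offset added to every channel", {
  set.seed(17)
  tr <- make_tone_trial(list(Fp1 = tone(10, 1), F7 = tone(20, 0.5)),
                        n = 1600, noise_sd = 0.05)
  tr_off <- tr
  tr_off$data <- tr$data + 3.7
  f1 <- fbp_features(preprocess_eeg(tr))
  f2 <- fbp_features(preprocess_eeg(tr_off))
  expect_equal(f1, f2, tolerance = 1e-6)
  a1 <- asymmetry_features(preprocess_eeg(tr))
  a2 <- asymmetry_features(preprocess_eeg(tr_off))
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("ISC scores are bounded, 15-long, and 1 for a target equal to the others' mean", {
  set.seed(27)
  # build three cubes directly: target = mean of the two others
  len <- 400
  mk <- function() {
    cube <- array(abs(rnorm(3 * 5 * len)) + 0.1, c(3, 5, len),
                  dimnames = list(graphsrc:::frontal_channels(),
                                  eeg_bands()$band, NULL))
    # smooth in time so lagged correlations are well behaved
    for (i in 1:3) for (b in 1:5) cube[i, b, ] <- stats::filter(cube[i, b, ],
                                                                rep(1/20, 20),
                                                                circular = TRUE)
    cube
  }
  c2 <- mk(); c3 <- mk()
  c1 <- (c2 + c3) / 2
  sc <- isc_scores(list(c1, c2, c3), target = 1, rate = 100)
  expect_length(sc, 15)
  expect_equal(unname(sc), rep(1, 15), tolerance = 1e-8)
  sc2 <- isc_scores(list(c2, c1, c3), target = 1, rate = 100)
  expect_true(all(sc2 >= -1 - 1e-10 & sc2 <= 1 + 1e-10))
})

test_that("a negated target gives correlation -1 at lag 0; the lag max is reported", {
  len <- 300
  base <- array(rep(sin(seq_len(len) / 10), each = 15), c(3, 5, len))
  neg <- -base
  # max over lags of cor(-s(t), s(t+l)) for a sinusoid reaches +1 at a half-period shift
  sc <- isc_scores(list(neg, base, base), target = 1, rate = 100, max_lag_s = 2)
  expect_true(all(sc <= 1 + 1e-10))
  # with the lag window collapsed to zero the score is the lag-0 correlation, -1
  sc0 <- isc_scores(list(neg, base, base), target = 1, rate = 100, max_lag_s = 0)
  expect_equal(unname(sc0), rep(-1, 15), tolerance = 1e-10)
})

test_that("constant band-power series give ISC 0 with a warning", {
  len <- 120
  flat <- array(1, c(3, 5, len))
  # the underlying reduction warns on degenerate series; isc_scores emits one
  # warning per channel-band pair, silenced here
  expect_warning(graphsrc:::max_lagged_cor(rep(1, 120), rep(1, 120), 5),
                 "constant")
  sc <- suppressWarnings(isc_scores(list(flat, flat, flat), target = 1,
                                    rate = 100))
  expect_equal(unname(sc), rep(0, 15))
})

test_that("the fast lagged correlation matches per-lag cor() calls", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(60:200, 1); L <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(graphsrc:::max_lagged_cor(x, y, L),
                 naive_max_lagged_cor(x, y, L), tolerance = 1e-10)
  }
})

test_that("rank transform is descending with averaged ties", {
  expect_equal(rank_across_viewings(c(5, 4, 3, 2, 1, 0)), 1:6)
  expect_equal(rank_across_viewings(rep(2, 6)), rep(3.5, 6))
  expect_equal(rank_across_viewings(c(1, 3, 2, 6, 5, 4)), c(6, 4, 5, 1, 2, 3))
})

test_that("assembled feature vector has the fixed 35-length layout", {
  f <- assemble_features(rep(0.1, 15), rep(0.2, 5), rep(0.3, 15))
  expect_length(f, 35)
  expect_error(assemble_features(rep(0, 14), rep(0, 5), rep(0, 15)))
  expect_error(assemble_features(rep(NA_real_, 15), rep(0, 5), rep(0, 15)),
               "finite")
})

test_that("trial validation enforces the montage and minimum duration", {
  dat <- matrix(0, 8, 900)
  expect_error(eeg_trial(dat, rate = 500), "2 s")
  dat2 <- matrix(0, 7, 1200)
  expect_error(eeg_trial(dat2, rate = 500,
                         channel_names = setdiff(eeg_channel_names(), "Cz")),
               "Cz")
})
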