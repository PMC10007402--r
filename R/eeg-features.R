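# EEG feature pipeline: preprocessing (Cz re-reference, zero-phase high-pass,
# 50 Hz notch), highly overlapped spectrogram band powers, frontal band-power
# features, F7-F8 hemispheric asymmetry, inter-subject correlations, and a
# rank-across-products transform. Yields a 35-dimensional feature vector per
# commercial viewing: 15 FBP + 5 asymmetry + 15 ISC.

#' Canonical EEG band definitions
#'
#' Delta 0.5-4, Theta 4-7.5, Alpha 8-12, Beta 13-25, Gamma 26-40 Hz.
#' A spectrogram bin belongs to a band when its centre frequency lies in
#' `[lo, hi)`.
#'
#' @return a data frame with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 13, 26),
             hi = c(4, 7.5, 12, 25, 40))
}

# representative tone per band used by the synthetic generator
band_center_tones <- function() c(2.25, 5.75, 10, 19, 33)

#' Standard 8-channel frontal montage
#' @return character vector of channel names.
#' @export
eeg_channel_names <- function() c("F7", "Fp1", "Fpz", "Fp2", "F8", "Fz", "Cz", "Pz")

# frontal electrodes used for FBP and ISC features, in feature order
frontal_channels <- function() c("Fp1", "Fpz", "Fp2")

#' Construct an EEG trial object
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate in samples/s (default 500).
#' @param channel_names character vector naming the rows; must contain the
#'   eight montage channels F7, Fp1, Fpz, Fp2, F8, Fz, Cz, Pz.
#' @param participant_id,product_id,viewing_id integer identifiers of the
#'   recording (participant, commercial/product in 1..6, viewing in 1..3).
#' @return an object of class `"eeg_trial"`.
#' @export
eeg_trial <- function(data, rate = 500, channel_names = eeg_channel_names(),
                      participant_id = 1L, product_id = 1L, viewing_id = 1L) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("EEG data must not contain NA")
  if (length(channel_names) != nrow(data))
    stop("need one channel name per row of 'data'")
  missing_ch <- setdiff(eeg_channel_names(), channel_names)
  if (length(missing_ch))
    stop("missing required channel(s): ", paste(missing_ch, collapse = ", "))
  if (ncol(data) < 2 * rate)
    stop("trial must contain at least 2 s of samples (one spectrogram window)")
  rownames(data) <- channel_names
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 participant_id = as.integer(participant_id),
                 product_id = as.integer(product_id),
                 viewing_id = as.integer(viewing_id)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat("EEG trial: ", nrow(x$data), " channels x ", ncol(x$data), " samples @ ",
      x$rate, " Hz (", format(ncol(x$data) / x$rate, digits = 4), " s)\n", sep = "")
  cat("  participant ", x$participant_id, ", product ", x$product_id,
      ", viewing ", x$viewing_id, "\n", sep = "")
  invisible(x)
}

#' Preprocess an EEG trial
#'
#' Re-references every channel to Cz (subtracts the Cz trace, leaving Cz at
#' zero), removes each channel's mean, applies a zero-phase high-pass at
#' 0.1 Hz (order-2 Butterworth run forward and backward, i.e. a 4th-order
#' zero-phase response), and a zero-phase 50 Hz notch (biquad, quality
#' factor 30). Artifact removal by ICA or visual inspection is not
#' performed; callers supply clean or synthetic data.
#'
#' @param trial an [eeg_trial()].
#' @param highpass_hz high-pass cutoff (default 0.1).
#' @param notch_hz notch centre frequency (default 50).
#' @param notch_q notch quality factor (default 30).
#' @return the preprocessed [eeg_trial()].
#' @export
preprocess_eeg <- function(trial, highpass_hz = 0.1, notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (!"Cz" %in% trial$channel_names) stop("reference channel Cz is missing")
  d <- trial$data
  cz <- d["Cz", ]
  d <- sweep(d, 2L, cz, "-")
  d <- d - rowMeans(d)
  fs <- trial$rate
  hp <- signal::butter(2, highpass_hz / (fs / 2), type = "high")
  # biquad notch: b = [1, -2cos(w0), 1], a = [1+alpha, -2cos(w0), 1-alpha]
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * notch_q)
  nb <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  na_ <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  for (i in seq_len(nrow(d))) {
    if (all(d[i, ] == 0)) next
    d[i, ] <- signal::filtfilt(hp, d[i, ])
    d[i, ] <- signal::filtfilt(filt = nb, a = na_, x = d[i, ])
  }
  out <- trial
  out$data <- d
  out
}

# Hann-windowed short-time band energies at hop 1. Returns a matrix
# n_bands x n_windows of summed |FFT|^2 over the bins whose centre frequency
# lies in [lo, hi). Computed in blocks of windows to bound memory.
stft_band_energies <- function(x, rate, window = NULL, bands = eeg_bands(),
                               block = 1024L) {
  if (is.null(window)) window <- 2L * rate        # 2 s
  n <- length(x)
  if (n < window) stop("signal shorter than one spectrogram window")
  nw <- n - window + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / window)  # periodic Hann
  freqs <- (0:(window - 1)) * rate / window
  half <- seq_len(window %/% 2 + 1)
  bidx <- lapply(seq_len(nrow(bands)), function(b)
    half[freqs[half] >= bands$lo[b] & freqs[half] < bands$hi[b]])
  out <- matrix(0, nrow(bands), nw)
  start <- 1L
  while (start <= nw) {
    end <- min(start + block - 1L, nw)
    idx <- start:end
    seg <- matrix(x[outer(0:(window - 1L), idx, "+")], window) * win
    sp <- Mod(stats::mvfft(seg))^2
    for (b in seq_len(nrow(bands)))
      out[b, idx] <- colSums(sp[bidx[[b]], , drop = FALSE])
    start <- end + 1L
  }
  rownames(out) <- bands$band
  out
}

#' Band-power time series of one channel
#'
#' Short-time spectrum with a 2 s (`2 * rate` samples) Hann window advanced
#' one sample at a time (maximal overlap); per window, the power of the
#' frequency bins whose centre lies inside the band is summed.
#'
#' @param trial a (preprocessed) [eeg_trial()].
#' @param channel channel name.
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return numeric vector of length `samples - window + 1`.
#' @export
band_power_series <- function(trial, channel, band) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (!channel %in% trial$channel_names) stop("unknown channel: ", channel)
  bands <- eeg_bands()
  if (!band %in% bands$band) stop("unknown band: ", band)
  e <- stft_band_energies(trial$data[channel, ], trial$rate)
  e[band, ]
}

# all 5-band power series for a set of channels: array [channel, band, time]
band_power_cube <- function(trial, channels = frontal_channels()) {
  bands <- eeg_bands()$band
  first <- stft_band_energies(trial$data[channels[1], ], trial$rate)
  cube <- array(NA_real_, c(length(channels), length(bands), ncol(first)),
                dimnames = list(channels, bands, NULL))
  cube[1, , ] <- first
  for (i in seq_along(channels)[-1])
    cube[i, , ] <- stft_band_energies(trial$data[channels[i], ], trial$rate)
  cube
}

# log floor keeps log10 finite on silent synthetic channels
log_power <- function(p, floor = 1e-12) log10(p + floor)

#' Frontal band-power features (15 values)
#'
#' Mean over time of `log10(band power + 1e-12)` for each of the three
#' prefrontal channels Fp1, Fpz, Fp2 crossed with the five bands
#' (channel-major order: Fp1-delta ... Fp1-gamma, Fpz-..., Fp2-...).
#'
#' @param trial a preprocessed [eeg_trial()].
#' @return named numeric vector of length 15.
#' @export
fbp_features <- function(trial) {
  fbp_from_cube(band_power_cube(trial, frontal_channels()))
}

fbp_from_cube <- function(cube) {
  bands <- eeg_bands()$band
  out <- numeric(0)
  for (ch in frontal_channels())
    for (b in bands)
      out[paste0("fbp_", ch, "_", b)] <- mean(log_power(cube[ch, b, ]))
  out
}

#' Hemispheric asymmetry features (5 values)
#'
#' Per band, the mean log10 band power at F7 minus the same at F8; the
#' alpha-band entry indexes approach-withdrawal tendency. Order
#' delta..gamma.
#'
#' @param trial a preprocessed [eeg_trial()].
#' @return named numeric vector of length 5.
#' @export
asymmetry_features <- function(trial) {
  e7 <- stft_band_energies(trial$data["F7", ], trial$rate)
  e8 <- stft_band_energies(trial$data["F8", ], trial$rate)
  bands <- eeg_bands()$band
  out <- rowMeans(log_power(e7)) - rowMeans(log_power(e8))
  names(out) <- paste0("asym_", bands)
  out
}

#' Inter-subject correlation scores (15 values)
#'
#' For one product viewing, correlates the target participant's band-power
#' time course (per frontal channel x band) with the average of all other
#' participants' courses. The normalized (Pearson) cross-correlation is
#' evaluated at every lag within `max_lag_s` seconds and the maximum over
#' lags is the score, giving one value per frontal channel x band.
#'
#' @param cohort list of band-power cubes (`[channel, band, time]` arrays,
#'   as produced internally from [eeg_trial()] objects, or the trials
#'   themselves), one per participant, equal time length.
#' @param target index of the target participant in `cohort`.
#' @param rate sampling rate of the power series in samples/s (hop is one
#'   sample, so this is the EEG rate; default 500).
#' @param max_lag_s lag window half-width in seconds (default 2).
#' @return named numeric vector of length 15, each in `[-1, 1]`.
#' @export
isc_scores <- function(cohort, target, rate = 500, max_lag_s = 2) {
  if (length(cohort) < 2L) stop("ISC needs at least 2 participants")
  cubes <- lapply(cohort, function(x)
    if (inherits(x, "eeg_trial")) band_power_cube(x) else x)
  len <- unique(vapply(cubes, function(c) dim(c)[3], integer(1)))
  if (length(len) != 1L) stop("all participants need equal-length power series")
  chans <- frontal_channels(); bands <- eeg_bands()$band
  others <- cubes[-target]
  tgt <- cubes[[target]]
  max_lag <- min(round(max_lag_s * rate), len - 2L)
  out <- numeric(0)
  for (ch in seq_along(chans)) {
    for (b in seq_along(bands)) {
      a <- tgt[ch, b, ]
      m <- Reduce(`+`, lapply(others, function(c) c[ch, b, ])) / length(others)
      out[paste0("isc_", chans[ch], "_", bands[b])] <- max_lagged_cor(a, m, max_lag)
    }
  }
  out
}

# max over lags |l| <= max_lag of the Pearson correlation between x[t] and
# y[t + l]; constant overlapping segments give 0 (with one warning upstream).
# The lag sweep uses one FFT cross-correlation for the product sums and
# cumulative sums for the per-lag means/variances, equivalent to calling
# cor() on the overlapping segments at every lag.
max_lagged_cor <- function(x, y, max_lag) {
  n <- length(x)
  max_lag <- min(max_lag, n - 2L)
  npad <- stats::nextn(2L * n, 2)
  xp <- c(x, numeric(npad - n)); yp <- c(y, numeric(npad - n))
  # cc[l] = sum_t x[t] y[t + l] for l = 0..n-1 at index l+1, l<0 at npad+l+1
  cc <- Re(stats::fft(Conj(stats::fft(xp)) * stats::fft(yp), inverse = TRUE)) / npad
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  cor_at <- function(l) {        # correlation of x[1..n-a] with y shifted by l
    if (l >= 0) {
      m <- n - l
      sx <- cx[m]; sx2 <- cx2[m]
      off_y <- if (l > 0) cy[l] else 0; off_y2 <- if (l > 0) cy2[l] else 0
      sy <- cy[n] - off_y; sy2 <- cy2[n] - off_y2
      sxy <- cc[l + 1L]
    } else {
      m <- n + l
      sy <- cy[m]; sy2 <- cy2[m]
      sx <- cx[n] - cx[-l]; sx2 <- cx2[n] - cx2[-l]
      sxy <- cc[npad + l + 1L]
    }
    vx <- sx2 - sx^2 / m
    vy <- sy2 - sy^2 / m
    if (vx <= 1e-12 * max(sx2, 1) || vy <= 1e-12 * max(sy2, 1)) return(NA_real_)
    (sxy - sx * sy / m) / sqrt(vx * vy)
  }
  rs <- vapply((-max_lag):max_lag, cor_at, numeric(1))
  if (all(is.na(rs))) {
    warning("constant band-power series: ISC score defined as 0")
    return(0)
  }
  max(rs, na.rm = TRUE)
}

#' Rank values across the six products
#'
#' Descending rank: the highest value receives rank 1, the lowest rank
#' `length(values)` (6 in the standard design); ties receive the mean of the
#' tied ranks. Applied feature-wise within a participant across products
#' after averaging a product's viewings.
#'
#' @param values numeric vector, one value per product.
#' @return numeric ranks of the same length.
#' @export
rank_across_viewings <- function(values) {
  if (anyNA(values)) stop("values must be finite")
  rank(-values, ties.method = "average")
}

#' Assemble the 35-dimensional feature vector
#'
#' Concatenates frontal band powers (15), hemispheric asymmetry (5), and
#' inter-subject correlations (15), in that fixed order.
#'
#' @param fbp,asymmetry,isc the three feature blocks.
#' @return named numeric vector of length 35.
#' @export
assemble_features <- function(fbp, asymmetry, isc) {
  stopifnot(length(fbp) == 15L, length(asymmetry) == 5L, length(isc) == 15L)
  out <- c(fbp, asymmetry, isc)
  if (!all(is.finite(out))) stop("assembled feature vector contains non-finite values")
  out
}

#' Extract the full feature table from a set of trials
#'
#' Preprocesses every trial, computes per-trial frontal band powers and
#' asymmetry, groups trials by (product, viewing) to compute leave-one-out
#' inter-subject correlations, and assembles one 35-feature row per trial.
#'
#' @param trials list of [eeg_trial()] objects covering all participants,
#'   products, and viewings (each product x viewing cell needs >= 2
#'   participants for the ISC block).
#' @param preprocess logical; run [preprocess_eeg()] first (default TRUE).
#' @return a data frame with columns `participant`, `product`, `viewing`
#'   and the 35 named feature columns.
#' @export
feature_table <- function(trials, preprocess = TRUE) {
  stopifnot(length(trials) >= 2L)
  if (preprocess) trials <- lapply(trials, preprocess_eeg)
  meta <- data.frame(
    participant = vapply(trials, function(t) t$participant_id, integer(1)),
    product = vapply(trials, function(t) t$product_id, integer(1)),
    viewing = vapply(trials, function(t) t$viewing_id, integer(1)))
  cubes <- lapply(trials, band_power_cube)
  n <- length(trials)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fbp <- fbp_from_cube(cubes[[i]])
    asym <- asymmetry_features(trials[[i]])
    peers <- which(meta$product == meta$product[i] & meta$viewing == meta$viewing[i])
    if (length(peers) < 2L)
      stop("product ", meta$product[i], " viewing ", meta$viewing[i],
           " has fewer than 2 participants; ISC undefined")
    isc <- isc_scores(cubes[peers], target = match(i, peers),
                      rate = trials[[i]]$rate)
    rows[[i]] <- assemble_features(fbp, asym, isc)
  }
  cbind(meta, as.data.frame(do.call(rbind, rows)))
}

#' Rank-transform a feature table across products
#'
#' Within each participant, averages a product's viewings feature-wise and
#' replaces each feature value by its descending rank across the products
#' (ties averaged). Returns one row per participant x product.
#'
#' @param ft a feature table from [feature_table()].
#' @return a data frame with `participant`, `product` and the ranked
#'   feature columns.
#' @export
rank_feature_table <- function(ft) {
  feat_cols <- setdiff(names(ft), c("participant", "product", "viewing"))
  out <- list()
  for (su in sort(unique(ft$participant))) {
    sub <- ft[ft$participant == su, , drop = FALSE]
    prods <- sort(unique(sub$product))
    avg <- t(vapply(prods, function(pr)
      colMeans(sub[sub$product == pr, feat_cols, drop = FALSE]),
      numeric(length(feat_cols))))
    ranked <- apply(avg, 2L, rank_across_viewings)
    if (is.null(dim(ranked))) ranked <- matrix(ranked, nrow = length(prods))
    colnames(ranked) <- feat_cols
    out[[length(out) + 1L]] <- cbind(
      data.frame(participant = su, product = prods), as.data.frame(ranked))
  }
  do.call(rbind, out)
}
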