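# Desk-scale synthetic data with the statistical structure the classifier
# assumes: (i) class-conditional union-of-subspaces feature vectors, and
# (ii) band-limited oscillatory multichannel EEG with known per-band power
# and controllable inter-participant coupling.

#' Specification for union-of-subspaces feature data
#'
#' @param p ambient feature dimension.
#' @param C number of classes.
#' @param d subspace dimension per class (`d < p`).
#' @param n_per_class samples per class (split 50/50 into train/test).
#' @param noise_sd standard deviation of the added isotropic Gaussian noise.
#' @param subspace_angle_control number in `[0, 1]`: 0 draws mutually
#'   orthogonal class bases, 1 collapses all classes onto one shared basis;
#'   intermediate values interpolate.
#' @param seed RNG seed.
#' @return a list of class `"subspace_spec"`.
#' @export
subspace_spec <- function(p = 20, C = 3, d = 2, n_per_class = 20,
                          noise_sd = 0.05, subspace_angle_control = 0,
                          seed = 1L) {
  stopifnot(p >= 1, C >= 1, d >= 1, d < p, n_per_class >= d, noise_sd >= 0,
            subspace_angle_control >= 0, subspace_angle_control <= 1)
  if (subspace_angle_control == 0 && d * C > p)
    stop("d * C > p: mutually orthogonal class bases are impossible; ",
         "raise p or subspace_angle_control")
  structure(list(p = as.integer(p), C = as.integer(C), d = as.integer(d),
                 n_per_class = as.integer(n_per_class), noise_sd = noise_sd,
                 subspace_angle_control = subspace_angle_control,
                 seed = as.integer(seed)),
            class = "subspace_spec")
}

# orthonormal basis of the column span via QR
orth <- function(m) qr.Q(qr(m))[, seq_len(ncol(m)), drop = FALSE]

#' Generate class-conditional union-of-subspaces feature data
#'
#' Each class c gets an orthonormal basis `U_c` (p x d); samples are
#' `U_c %*% coeffs + noise` with standard normal coefficients. With
#' `subspace_angle_control = 0` the class bases occupy mutually orthogonal
#' subspaces; as it grows toward 1 the bases are pulled toward a single
#' shared basis. Deterministic per seed; samples are split 50/50 into
#' train/test within each class.
#'
#' @param spec a [subspace_spec()].
#' @return list with `x_train`, `labels_train`, `x_test`, `labels_test`
#'   (feature matrices are p x n, one column per sample) and `bases`
#'   (list of the C class bases).
#' @export
simulate_subspace_data <- function(spec = subspace_spec()) {
  stopifnot(inherits(spec, "subspace_spec"))
  set.seed(spec$seed)
  p <- spec$p; C <- spec$C; d <- spec$d; npc <- spec$n_per_class
  t <- spec$subspace_angle_control

  shared <- orth(matrix(stats::rnorm(p * d), p, d))
  if (t == 0) {
    Q <- orth(matrix(stats::rnorm(p * d * C), p, d * C))
    bases <- lapply(seq_len(C), function(c) Q[, ((c - 1) * d + 1):(c * d), drop = FALSE])
  } else {
    bases <- lapply(seq_len(C), function(c) {
      own <- orth(matrix(stats::rnorm(p * d), p, d))
      orth((1 - t) * own + t * shared)
    })
  }

  n_train <- npc %/% 2L + npc %% 2L
  n_test <- npc - n_train
  xs <- vector("list", C); lab <- vector("list", C)
  for (c in seq_len(C)) {
    coeffs <- matrix(stats::rnorm(d * npc), d, npc)
    s <- bases[[c]] %*% coeffs
    if (spec$noise_sd > 0)
      s <- s + matrix(stats::rnorm(p * npc, sd = spec$noise_sd), p, npc)
    xs[[c]] <- s
    lab[[c]] <- rep(c, npc)
  }
  x_train <- do.call(cbind, lapply(xs, function(m) m[, seq_len(n_train), drop = FALSE]))
  x_test <- if (n_test > 0)
    do.call(cbind, lapply(xs, function(m) m[, n_train + seq_len(n_test), drop = FALSE]))
  else matrix(numeric(0), p, 0)
  list(x_train = x_train,
       labels_train = rep(seq_len(C), each = n_train),
       x_test = x_test,
       labels_test = rep(seq_len(C), each = n_test),
       bases = bases)
}

#' Specification for synthetic multichannel oscillatory EEG
#'
#' Emulates a commercial-viewing design: `n_participants` participants each
#' view `n_products` products `n_viewings` times; each trial is a sum of
#' band-centred sinusoids with product-specific amplitudes plus white noise,
#' and a participant-shared latent amplitude modulation (strength =
#' `coupling`) induces nonzero inter-subject correlation.
#'
#' @param n_participants number of participants.
#' @param n_products number of products/commercials (default 6).
#' @param n_viewings viewings per product (default 3).
#' @param duration_s trial length in seconds (>= 4).
#' @param rate sampling rate in Hz (default 500).
#' @param amplitudes matrix `n_products x 5` of per-band sinusoid amplitudes
#'   (columns Delta..Gamma), or `NULL` for a default profile in which each
#'   product emphasizes a different band.
#' @param coupling participant-coupling coefficient in `[0, 1]`: the
#'   fraction of the band-amplitude modulation shared across participants.
#' @param noise_sd white-noise standard deviation.
#' @param seed RNG seed.
#' @return a list of class `"synthetic_eeg_spec"`.
#' @export
synthetic_eeg_spec <- function(n_participants = 4, n_products = 6,
                               n_viewings = 3, duration_s = 4, rate = 500,
                               amplitudes = NULL, coupling = 0.5,
                               noise_sd = 0.1, seed = 1L) {
  stopifnot(n_participants >= 1, n_products >= 1, n_viewings >= 1,
            duration_s >= 4, rate > 0, coupling >= 0, coupling <= 1,
            noise_sd >= 0)
  if (is.null(amplitudes)) {
    amplitudes <- matrix(0.5, n_products, 5)
    for (pr in seq_len(n_products))
      amplitudes[pr, ((pr - 1) %% 5) + 1] <- 2
  }
  amplitudes <- as.matrix(amplitudes)
  stopifnot(nrow(amplitudes) == n_products, ncol(amplitudes) == 5,
            all(amplitudes >= 0))
  structure(list(n_participants = as.integer(n_participants),
                 n_products = as.integer(n_products),
                 n_viewings = as.integer(n_viewings),
                 duration_s = duration_s, rate = rate,
                 amplitudes = amplitudes, coupling = coupling,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_eeg_spec")
}

#' Generate synthetic oscillatory EEG trials
#'
#' Each trial is built per channel as a sum over the five canonical bands of
#' a sinusoid at the band's centre tone (2.25, 5.75, 10, 19, 33 Hz) whose
#' amplitude is the product-specific profile value times a slowly varying
#' positive modulation. The modulation is a convex mix of a cohort-shared
#' component and a participant-private component, with weight `coupling` on
#' the shared part, so that `coupling = 1, noise_sd = 0` yields identical
#' band-power time courses across participants (perfect inter-subject
#' correlation). White Gaussian noise is added per sample. Channel layout is
#' the 8-electrode frontal montage (F7, Fp1, Fpz, Fp2, F8, Fz, Cz, Pz); the
#' Cz reference channel is generated as zeros.
#'
#' @param spec a [synthetic_eeg_spec()].
#' @return a list of [eeg_trial()] objects, one per
#'   participant x product x viewing.
#' @export
simulate_eeg <- function(spec = synthetic_eeg_spec()) {
  stopifnot(inherits(spec, "synthetic_eeg_spec"))
  set.seed(spec$seed)
  ns <- round(spec$duration_s * spec$rate)
  tt <- (seq_len(ns) - 1) / spec$rate
  tones <- band_center_tones()
  chans <- eeg_channel_names()
  n_ch <- length(chans)
  trials <- vector("list", spec$n_participants * spec$n_products * spec$n_viewings)
  idx <- 0L
  # per-channel phase offsets, fixed across participants so that shared
  # modulation really aligns the signals
  phase <- matrix(stats::runif(n_ch * 5, 0, 2 * pi), n_ch, 5)
  # channel gains: frontal channels carry the signal; Cz stays at zero (reference)
  gain <- rep(1, n_ch); gain[chans == "Cz"] <- 0
  for (pr in seq_len(spec$n_products)) {
    for (vw in seq_len(spec$n_viewings)) {
      # cohort-shared slow latent modulation for this product viewing; one
      # series for all bands so band-power ratios track the amplitude profile
      shared_mod <- 1 + 0.5 * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
      for (su in seq_len(spec$n_participants)) {
        own_mod <- 1 + 0.5 * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
        mod <- spec$coupling * shared_mod + (1 - spec$coupling) * own_mod
        dat <- matrix(0, n_ch, ns)
        for (ch in seq_len(n_ch)) {
          if (gain[ch] == 0) next
          sig <- numeric(ns)
          for (b in seq_len(5)) {
            amp <- spec$amplitudes[pr, b]
            if (amp == 0) next
            sig <- sig + amp * mod * sin(2 * pi * tones[b] * tt + phase[ch, b])
          }
          dat[ch, ] <- sig
        }
        if (spec$noise_sd > 0)
          dat <- dat + matrix(stats::rnorm(n_ch * ns, sd = spec$noise_sd), n_ch, ns)
        dat[chans == "Cz", ] <- 0
        idx <- idx + 1L
        trials[[idx]] <- eeg_trial(dat, rate = spec$rate, channel_names = chans,
                                   participant_id = su, product_id = pr,
                                   viewing_id = vw)
      }
    }
  }
  trials
}
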