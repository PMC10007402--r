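# EEG fixtures built in code at test time.

# multichannel trial with chosen per-channel sinusoids:
# tones = named list channel -> matrix with columns freq, amp
make_tone_trial <- function(tones = list(), n = 1500, rate = 500,
                            noise_sd = 0, seed = 1,
                            participant_id = 1, product_id = 1, viewing_id = 1) {
  set.seed(seed)
  ch <- eeg_channel_names()
  tt <- (0:(n - 1)) / rate
  dat <- matrix(rnorm(length(ch) * n, sd = max(noise_sd, 1e-9)), length(ch), n)
  rownames(dat) <- ch
  for (nm in names(tones)) {
    spec <- tones[[nm]]
    for (r in seq_len(nrow(spec)))
      dat[nm, ] <- dat[nm, ] + spec[r, "amp"] * sin(2 * pi * spec[r, "freq"] * tt)
  }
  eeg_trial(dat, rate = rate, participant_id = participant_id,
            product_id = product_id, viewing_id = viewing_id)
}

tone <- function(freq, amp = 1) matrix(c(freq, amp), 1, dimnames = list(NULL, c("freq", "amp")))

# minimal EDF writer (continuous, 16-bit), used only to build read_edf fixtures
write_tiny_edf <- function(path, data, rate, labels) {
  ns <- nrow(data)
  n_samp <- ncol(data)
  record_dur <- 1
  spr <- rate * record_dur
  stopifnot(n_samp %% spr == 0)
  n_rec <- n_samp / spr
  phys_min <- apply(data, 1, min) - 1e-6
  phys_max <- apply(data, 1, max) + 1e-6
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, eos = NULL)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr(as.character(record_dur), 8)
  wr(as.character(ns), 4)
  for (l in labels) wr(paste("EEG", l), 16)
  for (i in 1:ns) wr("test transducer", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(format(phys_min[i], digits = 6), 8)
  for (i in 1:ns) wr(format(phys_max[i], digits = 6), 8)
  for (i in 1:ns) wr(as.character(dig_min[i]), 8)
  for (i in 1:ns) wr(as.character(dig_max[i]), 8)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr(as.character(spr), 8)
  for (i in 1:ns) wr("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- data[i, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((seg - phys_min[i]) / gain[i] + dig_min[i]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
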