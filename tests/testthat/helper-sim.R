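# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so individual suites stay fast.

# A compact contaminated trial: nc channels, 3 gamma-burst sources + 1
# audio-like artifact, 2 s @ 1 kHz, onset at 0.5 s.
small_trial <- function(seed = 1, nc = 8, agr_db = 0, scenario = "mcas",
                        f0 = 150, duration = 2, mix_seed = seed + 7L) {
  simulate_trial(n_channels = nc, n_sources = 3, agr_db = agr_db,
                 scenario = scenario, f0 = f0, duration = duration,
                 fs = 1000, onset_time = 0.5, seed = seed,
                 mix_seed = mix_seed)
}

# Fast PCD configuration for unit tests (fewer restarts).
fast_cfg <- function(seed = 1, ...) {
  pcd_config(n_restarts = 4, seed = seed, ...)
}

# Coherence at (approximately) a single frequency, channel-averaged.
mean_coh_at <- function(X, ref, fs, f0, seg_len = 500) {
  X <- rbind(X)
  mean(apply(X, 1, function(ch) {
    m <- msce(ch, ref, fs, seg_len = seg_len)
    m$coh[which.min(abs(m$freq - f0))]
  }))
}

# Mean Welch-MSCE between two signals inside a band.
band_msce <- function(a, b, fs, band, seg_len = 500) {
  m <- msce(a, b, fs, seg_len = seg_len)
  sel <- m$freq >= band$lo & m$freq <= band$hi
  mean(m$coh[sel])
}

# Write a minimal single-record EDF file for reader tests.
write_test_edf <- function(path, X, fs, labels = NULL, rec_dur = 1,
                           spr = NULL) {
  nc <- nrow(X)
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nc))
  if (is.null(spr)) spr <- rep(round(fs * rec_dur), nc)
  n_rec <- ncol(X) / max(spr)
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wrt("0", 8); wrt("patient", 80); wrt("recording", 80)
  wrt("01.01.26", 8); wrt("00.00.00", 8)
  wrt(as.character(256 + 256 * nc), 8); wrt("", 44)
  wrt(as.character(n_rec), 8); wrt(as.character(rec_dur), 8)
  wrt(as.character(nc), 4)
  for (l in labels) wrt(l, 16)
  for (i in seq_len(nc)) wrt("", 80)      # transducer
  for (i in seq_len(nc)) wrt("uV", 8)
  for (i in seq_len(nc)) wrt("-1000", 8)  # phys min
  for (i in seq_len(nc)) wrt("1000", 8)   # phys max
  for (i in seq_len(nc)) wrt("-32768", 8)
  for (i in seq_len(nc)) wrt("32767", 8)
  for (i in seq_len(nc)) wrt("", 80)      # prefilter
  for (i in seq_len(nc)) wrt(as.character(spr[i]), 8)
  for (i in seq_len(nc)) wrt("", 32)
  # use the exact EDF physical/digital mapping so quantization is the only
  # error: gain = (phys_max - phys_min) / (dig_max - dig_min)
  gain <- 2000 / 65535
  offset <- -1000 - gain * (-32768)
  dig <- round((X - offset) / gain)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nc)) {
      idx <- (r - 1) * spr[i] + seq_len(spr[i])
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
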