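# Synthetic-data generators with known ground truth. The artifact source is
# an audio-like waveform; the neural sources are band-limited gamma noise
# with speech-locked envelopes. A random linear mix at a controlled
# artifact-to-physiological-gamma ratio (AGR) produces the contaminated
# recording.

#' Audio / artifact source parameters
#'
#' Defines the synthetic produced-audio waveform used both as the artifact
#' source and as the supervision signal. Three scenarios are supported:
#' `"sas"` (sinusoid at the voice fundamental plus white noise), `"cas"`
#' (colored noise: white noise spectrally shaped by an order-`filter_order`
#' Butterworth band-pass over `f0 +/- df`), and `"mcas"` (the colored-noise
#' audio gated by a syllable activation pattern that is 1 inside each
#' syllable window and 0 elsewhere).
#'
#' @param scenario one of `"sas"`, `"cas"`, `"mcas"`.
#' @param a0 sinusoid amplitude (a.u., SAS).
#' @param f0 voice fundamental frequency (Hz), in `[50, 250]`.
#' @param phi0 sinusoid phase (radians, SAS).
#' @param noise_sd white-noise standard deviation (a.u., SAS).
#' @param df band half-width (Hz) of the colored-noise passband (CAS/MCAS).
#' @param filter_order Butterworth order of the coloring response.
#' @param sigma colored-noise scale (a.u., CAS/MCAS).
#' @param syllable_onsets onsets of the syllable windows (s, MCAS).
#' @param syllable_dur syllable duration (s, MCAS).
#' @param duration trial duration (s).
#' @param fs sampling rate (Hz); must exceed `2 * (f0 + df)`.
#' @param seed integer RNG seed; generation is a pure function of the
#'   parameter set including the seed.
#' @return a validated parameter list of class `audio_params`.
#' @export
audio_params <- function(scenario = c("sas", "cas", "mcas"),
                         a0 = 1, f0 = 150, phi0 = 0, noise_sd = 0.1,
                         df = 8, filter_order = 25, sigma = 1,
                         syllable_onsets = c(0.5, 1.5, 2.5),
                         syllable_dur = 0.5,
                         duration = 3, fs = 1000, seed = 1) {
  scenario <- match.arg(scenario)
  if (f0 < 50 || f0 > 250)
    stop("f0 must lie in the voice range [50, 250] Hz")
  stopifnot(duration > 0, df > 0, filter_order >= 1)
  if (fs <= 2 * (f0 + df))
    stop("fs = ", fs, " Hz too low for a band up to ", f0 + df,
         " Hz (aliasing risk)")
  if (scenario == "mcas") {
    if (any(syllable_onsets < 0) ||
        any(syllable_onsets + syllable_dur > duration + 1e-9))
      stop("syllable windows must lie within [0, duration]")
  }
  structure(list(scenario = scenario, a0 = a0, f0 = f0, phi0 = phi0,
                 noise_sd = noise_sd, df = df, filter_order = filter_order,
                 sigma = sigma, syllable_onsets = syllable_onsets,
                 syllable_dur = syllable_dur, duration = duration,
                 fs = fs, seed = as.integer(seed)),
            class = "audio_params")
}

# Analytic magnitude response of an order-n Butterworth band-pass, evaluated
# on the FFT grid. Used to color white noise: a transfer-function (b, a)
# realization is numerically unstable at the high orders used for the
# colored-noise audio, while spectral shaping is exact and zero-phase.
butter_bandpass_gain <- function(f, lo, hi, order) {
  f0 <- sqrt(lo * hi)
  bw <- hi - lo
  wrp <- ifelse(f <= 0, Inf, (f^2 - f0^2) / (f * bw))
  1 / sqrt(1 + wrp^(2 * order))
}

color_noise <- function(noise, fs, lo, hi, order) {
  n <- length(noise)
  freqs <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) * fs / n
  gain <- butter_bandpass_gain(abs(freqs), lo, hi, order)
  Re(stats::fft(stats::fft(noise) * gain, inverse = TRUE) / n)
}

#' Generate a synthetic audio / artifact waveform
#'
#' @param params an [audio_params()] object.
#' @return list with `wave` (length `duration * fs`), `fs`, and `params`.
#' @export
gen_audio <- function(params) {
  stopifnot(inherits(params, "audio_params"))
  p <- params
  n <- round(p$duration * p$fs)
  tt <- (0:(n - 1)) / p$fs
  wave <- with_seed(p$seed, {
    switch(p$scenario,
      sas = p$a0 * sin(2 * pi * p$f0 * tt + p$phi0) +
        stats::rnorm(n, sd = p$noise_sd),
      cas = color_noise(p$sigma * stats::rnorm(n), p$fs,
                        p$f0 - p$df, p$f0 + p$df, p$filter_order),
      mcas = {
        cas <- color_noise(p$sigma * stats::rnorm(n), p$fs,
                           p$f0 - p$df, p$f0 + p$df, p$filter_order)
        m <- numeric(n)
        for (on in p$syllable_onsets) {
          idx <- tt >= on & tt < on + p$syllable_dur
          m[idx] <- 1
        }
        cas * m
      }
    )
  })
  list(wave = wave, fs = p$fs, params = p)
}

#' Surrogate gamma-source parameters
#'
#' Parameters of the band-limited noise source standing in for physiological
#' broadband gamma activity. The amplitude envelope is either sustained with
#' a periodic modulation, `as + ap * sin(2*pi*fp*t + phip)`, or a Gaussian
#' burst `a * exp(-(t - mu)^2 / (2 * (fwhm/2.355)^2))` time-locked to speech.
#' Optional phase-amplitude coupling multiplies the envelope by
#' `1 + pac_depth * cos(2*pi*pac_freq*t)`.
#'
#' @param envelope `"sustained_periodic"` or `"gaussian_burst"`.
#' @param as,ap,fp,phip sustained amplitude, periodic amplitude (must not
#'   exceed `as`), frequency (Hz) and phase (rad) of the periodic envelope.
#' @param a,mu,fwhm amplitude, center (s) and full width at half maximum (s)
#'   of the Gaussian burst.
#' @param band_lo,band_hi gamma band edges (Hz) of the noise carrier.
#' @param pac_depth coupling depth in `[0, 1]` (0 disables).
#' @param pac_freq coupling driver frequency (Hz).
#' @param seed integer RNG seed.
#' @return a validated parameter list of class `gamma_params`.
#' @export
gamma_params <- function(envelope = c("gaussian_burst", "sustained_periodic"),
                         as = 1, ap = 0.5, fp = 2, phip = 0,
                         a = 1, mu = 1, fwhm = 0.5,
                         band_lo = 60, band_hi = 200,
                         pac_depth = 0, pac_freq = 6, seed = 1) {
  envelope <- match.arg(envelope)
  stopifnot(pac_depth >= 0, pac_depth <= 1, band_lo < band_hi, fwhm > 0)
  if (envelope == "sustained_periodic" && as < ap)
    stop("envelope would go negative: as < ap")
  structure(list(envelope = envelope, as = as, ap = ap, fp = fp, phip = phip,
                 a = a, mu = mu, fwhm = fwhm, band_lo = band_lo,
                 band_hi = band_hi, pac_depth = pac_depth,
                 pac_freq = pac_freq, seed = as.integer(seed)),
            class = "gamma_params")
}

#' Generate a surrogate gamma source
#'
#' Band-limited noise in `[band_lo, band_hi]` Hz multiplied by the
#' speech-locked amplitude envelope defined in [gamma_params()].
#'
#' @param params a [gamma_params()] object.
#' @param duration duration (s).
#' @param fs sampling rate (Hz); `band_hi` must stay below `fs/2`.
#' @return numeric waveform of length `duration * fs`.
#' @export
gen_gamma_source <- function(params, duration, fs) {
  stopifnot(inherits(params, "gamma_params"))
  p <- params
  if (p$band_hi >= fs / 2) stop("band_hi must stay below fs/2")
  n <- round(duration * fs)
  if (n < 64) stop("duration too short for the band-limiting filter warm-up")
  tt <- (0:(n - 1)) / fs
  carrier <- with_seed(p$seed, stats::rnorm(n))
  carrier <- filter_bandpass(carrier, fs, p$band_lo, p$band_hi, order = 4)
  carrier <- carrier / stats::sd(carrier)
  env <- switch(p$envelope,
    sustained_periodic = p$as + p$ap * sin(2 * pi * p$fp * tt + p$phip),
    gaussian_burst = p$a * exp(-(tt - p$mu)^2 / (2 * (p$fwhm / 2.355)^2))
  )
  if (p$pac_depth > 0)
    env <- env * (1 + p$pac_depth * cos(2 * pi * p$pac_freq * tt))
  carrier * env
}

#' Mix neural and artifact sources into a simulated recording
#'
#' Rescales the artifact source so that the artifact-to-physiological-gamma
#' ratio, `AGR = 10*log10(P_a / P_g)` with `P_a` the artifact's mean Welch
#' power in the 60-200 Hz gamma band and `P_g` the mean such power across
#' neural sources, hits `agr_db` exactly; then projects all sources through
#' a random standard-normal mixing matrix.
#'
#' @param S_neural sources x samples matrix of neural source waveforms.
#' @param s_artifact artifact source waveform (same length).
#' @param agr_db target artifact-to-gamma ratio (dB).
#' @param n_channels number of simulated channels, at least
#'   `nrow(S_neural) + 1`.
#' @param fs sampling rate (Hz).
#' @param seed integer seed for the mixing matrix; a rank-deficient draw is
#'   redrawn from the next seed offset with a warning.
#' @return list with `recording` (a [recording()]) and `truth` (class
#'   `sim_truth`: `S_neural`, `s_artifact` as scaled and mixed, `A_mix`,
#'   `agr_db`, `fs`).
#' @export
mix_sources <- function(S_neural, s_artifact, agr_db, n_channels, fs,
                        seed = 1) {
  S_neural <- as.matrix(S_neural)
  ns <- nrow(S_neural)
  stopifnot(ncol(S_neural) == length(s_artifact), n_channels >= ns + 1)
  p_gamma <- mean(apply(S_neural, 1, band_power, fs = fs, lo = 60, hi = 200))
  p_art <- band_power(s_artifact, fs, 60, 200)
  scale <- sqrt(10^(agr_db / 10) * p_gamma / p_art)
  s_art <- s_artifact * scale
  n_src <- ns + 1L
  A <- NULL
  for (try in 0:9) {
    A_try <- with_seed(seed + try * 7919L,
                       matrix(stats::rnorm(n_channels * n_src), n_channels))
    sv <- svd(A_try)$d
    if (sv[length(sv)] / sv[1] > 1e-8) { A <- A_try; break }
    warning("rank-deficient mixing matrix draw; redrawing from substream ",
            try + 1)
  }
  if (is.null(A)) stop("could not draw a full-rank mixing matrix")
  X <- A %*% rbind(S_neural, s_art)
  rec <- recording(X, fs)
  truth <- structure(list(S_neural = S_neural, s_artifact = s_art,
                          A_mix = A, agr_db = agr_db, fs = fs),
                     class = "sim_truth")
  list(recording = rec, truth = truth)
}

#' Simulate one speech trial with ground truth
#'
#' Convenience wrapper building the study conditions used throughout the
#' package's benchmarks: gamma-burst neural sources time-locked to a
#' produced-speech onset, one audio-like artifact source, and a random mix
#' at a controlled AGR.
#'
#' @param n_channels number of channels.
#' @param n_sources number of gamma-burst neural sources.
#' @param agr_db artifact-to-gamma ratio (dB).
#' @param scenario audio scenario passed to [audio_params()].
#' @param f0,df artifact band parameters (Hz).
#' @param duration trial duration (s).
#' @param fs sampling rate (Hz).
#' @param onset_time produced-speech onset (s from trial start).
#' @param gamma_envelope `"gaussian_burst"` for speech-locked transient
#'   gamma (the realistic scenario) or `"sustained_periodic"` for tonically
#'   active, slowly modulated gamma (the toy scenarios).
#' @param seed integer seed; all per-source seeds derive from it.
#' @param mix_seed seed of the mixing matrix draw. Defaults to a per-trial
#'   value; pass the same value across trials of a session to emulate a
#'   fixed acquisition chain, which is what makes artifact phase
#'   relationships consistent across trials (and intertrial phase
#'   consistency able to detect them).
#' @return list with `trial` (a [trial_epoch()]: contaminated data + audio),
#'   `truth` (`sim_truth`), and `X_clean` (the artifact-free mixture).
#' @export
simulate_trial <- function(n_channels = 16, n_sources = 3, agr_db = 0,
                           scenario = "mcas", f0 = 150, df = 8,
                           duration = 3, fs = 1000, onset_time = 0.5,
                           gamma_envelope = c("gaussian_burst",
                                              "sustained_periodic"),
                           seed = 1, mix_seed = seed + 7L) {
  seed <- as.integer(seed)
  gamma_envelope <- match.arg(gamma_envelope)
  ap <- audio_params(scenario = scenario, f0 = f0, df = df,
                     duration = duration, fs = fs,
                     syllable_onsets = onset_time + c(0, 1, 2) *
                       min(1, (duration - onset_time - 0.5) / 2),
                     seed = seed)
  audio <- gen_audio(ap)$wave
  S <- if (gamma_envelope == "gaussian_burst") {
    # speech-locked bursts spread over the speech epoch, FWHM 0.5 s
    mus <- onset_time + seq(0.25, duration - onset_time - 0.5,
                            length.out = n_sources)
    t(vapply(seq_len(n_sources), function(i) {
      gp <- gamma_params(envelope = "gaussian_burst", a = 1, mu = mus[i],
                         fwhm = 0.5, seed = seed + 101L * i)
      gen_gamma_source(gp, duration, fs)
    }, numeric(round(duration * fs))))
  } else {
    # tonic gamma with slow periodic modulation, phases spread over sources
    t(vapply(seq_len(n_sources), function(i) {
      gp <- gamma_params(envelope = "sustained_periodic", as = 1, ap = 0.5,
                         fp = 2, phip = 2 * pi * (i - 1) / n_sources,
                         seed = seed + 101L * i)
      gen_gamma_source(gp, duration, fs)
    }, numeric(round(duration * fs))))
  }
  mix <- mix_sources(S, audio, agr_db, n_channels, fs,
                     seed = as.integer(mix_seed))
  X_clean <- mix$truth$A_mix[, seq_len(n_sources), drop = FALSE] %*% S
  trial <- trial_epoch(mix$recording, audio,
                       onset_index = round(onset_time * fs) + 1L, fs = fs)
  list(trial = trial, truth = mix$truth, X_clean = X_clean)
}
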