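#' Multichannel recording container
#'
#' A light container for a channels x samples voltage matrix with its
#' sampling rate, channel labels and per-channel modality tags (e.g. "ecog",
#' "lfp"). All spatial-filtering functions accept either a `recording` or a
#' bare matrix.
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector, one per channel.
#' @param modality optional character vector of per-channel modality tags.
#' @return an object of class `recording`.
#' @export
recording <- function(data, fs, channel_names = NULL, modality = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  nc <- nrow(data)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nc))
  stopifnot(length(channel_names) == nc)
  if (!is.null(modality)) stopifnot(length(modality) == nc)
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         modality = modality),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$modality))
    cat("modalities:", paste(unique(x$modality), collapse = ", "), "\n")
  invisible(x)
}

# Accept a recording or a plain matrix; return the channels x samples matrix.
channel_matrix <- function(X) {
  if (inherits(X, "recording")) X$data else as.matrix(X)
}

rec_fs <- function(X, fs = NULL) {
  if (inherits(X, "recording")) X$fs
  else if (!is.null(fs)) fs
  else stop("sampling rate `fs` required when input is a bare matrix")
}

#' Speech-artifact frequency band
#'
#' The narrow band `Fc +/- dFc` around the voice fundamental frequency where
#' the vibration artifact concentrates.
#'
#' @param fc center frequency (Hz).
#' @param dfc band half-extent (Hz); by convention the full width at half
#'   maximum of the spectral peak fitted to the audio.
#' @param fs sampling rate (Hz) used to validate the band against Nyquist.
#' @return an object of class `artifact_band` with fields `fc`, `dfc`,
#'   `lo`, `hi`.
#' @export
artifact_band <- function(fc, dfc, fs = NULL) {
  stopifnot(fc > 0, dfc > 0)
  lo <- fc - dfc
  hi <- fc + dfc
  if (lo <= 0) stop("band lower edge must be positive (fc = ", fc,
                    ", dfc = ", dfc, ")")
  if (!is.null(fs) && hi >= fs / 2)
    stop("band upper edge ", hi, " Hz reaches Nyquist (fs = ", fs, ")")
  structure(list(fc = fc, dfc = dfc, lo = lo, hi = hi),
            class = "artifact_band")
}

#' @export
print.artifact_band <- function(x, ...) {
  cat(sprintf("<artifact_band> Fc = %.2f Hz, dFc = %.2f Hz -> [%.2f, %.2f] Hz\n",
              x$fc, x$dfc, x$lo, x$hi))
  invisible(x)
}

#' Trial epoch around a produced-speech onset
#'
#' @param X channels x samples matrix (or `recording`).
#' @param audio produced-audio waveform, same length and rate as `X`.
#' @param onset_index 1-based sample index of the produced-speech onset.
#' @param fs sampling rate (Hz); taken from `X` when it is a `recording`.
#' @return an object of class `trial_epoch`.
#' @export
trial_epoch <- function(X, audio, onset_index, fs = NULL) {
  fs <- rec_fs(X, fs)
  Xm <- channel_matrix(X)
  stopifnot(length(audio) == ncol(Xm))
  stopifnot(onset_index >= 1, onset_index <= ncol(Xm))
  structure(list(X = Xm, audio = as.numeric(audio),
                 onset_index = as.integer(onset_index), fs = fs),
            class = "trial_epoch")
}
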