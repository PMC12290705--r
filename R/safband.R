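# Speech-artifact frequency band (SAFB) estimation from the produced audio:
# locate the voice fundamental (F0) as the dominant Welch-PSD peak in the
# 50-250 Hz range, then fit a Gaussian-plus-floor to the PSD around it and
# take the fitted mean and FWHM as band center and half-extent.
#
# Peak finding uses 0.5 s Welch segments: short speech epochs give too few
# 1 s segments for the 6 dB prominence rule to reject a flat spectrum
# reliably. The band-width fit keeps 1 s segments (1 Hz resolution).

#' Estimate the voice fundamental frequency from audio
#'
#' Finds the frequency of the largest prominent local maximum of the Welch
#' power spectrum of the detrended audio inside the search band. A peak
#' counts as prominent when it exceeds the in-band median PSD by 6 dB.
#'
#' @param audio audio waveform.
#' @param fs sampling rate (Hz).
#' @param search_lo,search_hi search band (Hz), default the 50-250 Hz voice
#'   range.
#' @param seg_len Welch segment length in samples (default 0.5 s, trading
#'   resolution for enough averages to make the prominence rule selective).
#' @return the peak frequency (Hz).
#' @export
estimate_f0 <- function(audio, fs, search_lo = 50, search_hi = 250,
                        seg_len = round(fs / 2)) {
  stopifnot(search_lo > 0, search_hi > search_lo, search_hi < fs / 2)
  p <- welch_psd(audio - mean(audio), fs, seg_len = seg_len)
  sel <- which(p$freq >= search_lo & p$freq <= search_hi)
  if (length(sel) < 3) stop("search band too narrow for the Welch grid")
  psd <- p$psd[sel]
  thresh <- stats::median(psd) * 10^(6 / 10)  # 6 dB over in-band median
  inner <- 2:(length(sel) - 1)
  is_peak <- psd[inner] > psd[inner - 1] & psd[inner] >= psd[inner + 1] &
    psd[inner] >= thresh
  if (!any(is_peak)) stop("no F0 peak found in [", search_lo, ", ",
                          search_hi, "] Hz")
  best <- inner[is_peak][which.max(psd[inner][is_peak])]
  p$freq[sel][best]
}

# Gaussian-plus-floor fit to a PSD window: psd ~ floor + amp*exp(-(f-mu)^2/(2*sd^2)).
# Exposed for direct testing against analytically constructed spectra.
#' Fit a Gaussian peak (plus constant floor) to a power spectrum
#'
#' @param freq frequency grid (Hz).
#' @param psd power spectral density on that grid.
#' @param f0_hint initial guess for the peak center (Hz).
#' @return list with `fc` (fitted mean, Hz), `fwhm` (Hz, `2.355 * sd`),
#'   `converged` (logical).
#' @export
fit_gaussian_peak <- function(freq, psd, f0_hint) {
  stopifnot(length(freq) == length(psd), length(freq) >= 5)
  floor0 <- stats::quantile(psd, 0.25, names = FALSE)
  amp0 <- max(psd) - floor0
  sd0 <- max(diff(freq)[1], (max(freq) - min(freq)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      psd ~ fl + amp * exp(-(freq - mu)^2 / (2 * s^2)),
      start = list(fl = floor0, amp = amp0, mu = f0_hint, s = sd0),
      lower = c(fl = -Inf, amp = 0, mu = min(freq), s = diff(freq)[1] / 10),
      upper = c(fl = Inf, amp = Inf, mu = max(freq), s = max(freq) - min(freq)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit))
    return(list(fc = f0_hint, fwhm = NA_real_, converged = FALSE))
  cf <- stats::coef(fit)
  list(fc = unname(cf["mu"]), fwhm = 2.355 * unname(cf["s"]),
       converged = TRUE)
}

#' Estimate the speech-artifact frequency band from audio
#'
#' Computes the Welch PSD of the audio, fits a Gaussian (plus constant
#' floor) in a window around `f0_hint`, and returns the band
#' `Fc +/- dFc` with `Fc` the fitted mean and `dFc` the fitted full width at
#' half maximum, floored at two frequency bins. Falls back to
#' `(f0_hint, 5 Hz)` with a warning when the fit does not converge.
#'
#' @param audio audio waveform.
#' @param fs sampling rate (Hz).
#' @param f0_hint center of the fit window (Hz); estimated with
#'   [estimate_f0()] when `NULL`.
#' @param window_hz half-width of the PSD window used for the fit (Hz).
#' @param seg_len Welch segment length in samples (default 1 s).
#' @return an [artifact_band()].
#' @export
estimate_safband <- function(audio, fs, f0_hint = NULL, window_hz = 25,
                             seg_len = NULL) {
  if (is.null(f0_hint)) f0_hint <- estimate_f0(audio, fs, seg_len = seg_len)
  p <- welch_psd(audio - mean(audio), fs, seg_len = seg_len)
  dfreq <- p$freq[2] - p$freq[1]
  sel <- p$freq >= f0_hint - window_hz & p$freq <= f0_hint + window_hz
  fit <- fit_gaussian_peak(p$freq[sel], p$psd[sel], f0_hint)
  if (!fit$converged) {
    warning("Gaussian peak fit did not converge; falling back to ",
            "(Fc = f0_hint, dFc = 5 Hz)")
    return(artifact_band(f0_hint, 5, fs = fs))
  }
  dfc <- max(fit$fwhm, 2 * dfreq)  # floor at 2 frequency bins
  artifact_band(fit$fc, dfc, fs = fs)
}
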