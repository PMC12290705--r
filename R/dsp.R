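# Shared signal-processing primitives: Welch spectra, analytic signal,
# zero-phase Butterworth filtering. All filters run forward-backward with
# odd-reflection padding so that no phase distortion is introduced (phase
# relationships with the audio are the quantity of interest downstream).

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Welch cross-spectral density
#'
#' Segment-averaged, Hann-windowed cross-spectral density between two equal
#' length signals. With `y = x` this is the Welch power spectral density.
#' Segments are mean-detrended before windowing.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default: 1 s of data, capped at
#'   the signal length).
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @return list with `freq` (Hz) and `csd` (complex density, one-sided).
#' @export
welch_csd <- function(x, y = x, fs, seg_len = NULL, overlap = 0.5) {
  stopifnot(length(x) == length(y), fs > 0)
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(fs))
  seg_len <- min(seg_len, n)
  if (seg_len < 8) stop("signal too short for spectral estimation")
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hann_window(seg_len)
  scale <- sum(w^2) * fs
  nf <- floor(seg_len / 2) + 1L
  acc <- complex(length.out = nf)
  for (s in starts) {
    idx <- s:(s + seg_len - 1L)
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx] - mean(y[idx])
    X <- stats::fft(w * xs)[1:nf]
    Y <- stats::fft(w * ys)[1:nf]
    acc <- acc + Conj(X) * Y
  }
  csd <- acc / (length(starts) * scale)
  # one-sided density: double everything except DC (and Nyquist when even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (seg_len %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / seg_len, csd = csd * dbl)
}

#' Welch power spectral density
#'
#' @inheritParams welch_csd
#' @return list with `freq` (Hz) and `psd` (real, one-sided density).
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  out <- welch_csd(x, x, fs, seg_len = seg_len, overlap = overlap)
  list(freq = out$freq, psd = Re(out$csd))
}

# Mean band power from a Welch PSD, integrating over [lo, hi] Hz.
band_power <- function(x, fs, lo, hi, seg_len = NULL) {
  p <- welch_psd(x, fs, seg_len = seg_len)
  sel <- p$freq >= lo & p$freq <= hi
  if (!any(sel)) stop("no frequency bins inside [", lo, ", ", hi, "] Hz")
  mean(p$psd[sel])
}

# FFT-based analytic signal of a real vector: x + i*Hilbert(x).
analytic_vector <- function(x) {
  if (anyNA(x)) stop("NaN/NA in input to analytic signal")
  n <- length(x)
  if (n < 8) stop("input too short for analytic signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Butterworth design with stability step-down: narrow bands at high order can
# put poles outside the unit circle in the (b, a) realization; reduce the
# order stepwise to 2 before giving up.
design_butter <- function(order, w, type) {
  for (ord in seq(order, 2)) {
    flt <- signal::butter(ord, w, type = type)
    poles <- polyroot(rev(flt$a))
    if (all(Mod(poles) < 1 - 1e-8)) return(flt)
  }
  stop("unstable Butterworth filter at all orders >= 2 for edges [",
       paste(signif(w, 4), collapse = ", "), "]")
}

# Forward-backward (zero-phase) filtering with odd-reflection edge padding.
# The pad must outlast the filter's zero-state transient, which decays with
# the largest pole radius r as r^t: use ~8 time constants of the slowest
# pole, not just a few taps.
zerophase_filter <- function(x, flt) {
  b <- flt$b; a <- flt$a
  n <- length(x)
  r <- max(Mod(polyroot(rev(a))))
  p_decay <- if (r < 1) ceiling(8 / (1 - r)) else n - 1L
  p <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), p_decay))
  ext <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- as.numeric(signal::filter(b, a, ext))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p + 1):(p + n)]
}

apply_rowwise <- function(X, fun) {
  if (is.null(dim(X))) return(fun(X))
  t(apply(X, 1, fun))
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param X numeric vector or channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz), `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass (effective order doubles with the
#'   forward-backward application); stepped down automatically if the design
#'   is unstable.
#' @return filtered data, same shape as `X`.
#' @export
filter_bandpass <- function(X, fs, lo, hi, order = 4) {
  stopifnot(lo > 0, lo < hi, hi < fs / 2)
  flt <- design_butter(order, c(lo, hi) / (fs / 2), "pass")
  apply_rowwise(X, function(x) zerophase_filter(x, flt))
}

#' Zero-phase Butterworth band-stop filter
#'
#' @inheritParams filter_bandpass
#' @return filtered data, same shape as `X`.
#' @export
filter_bandstop <- function(X, fs, lo, hi, order = 4) {
  stopifnot(lo > 0, lo < hi, hi < fs / 2)
  flt <- design_butter(order, c(lo, hi) / (fs / 2), "stop")
  apply_rowwise(X, function(x) zerophase_filter(x, flt))
}

#' Zero-phase Butterworth high-pass filter
#'
#' @inheritParams filter_bandpass
#' @param cutoff cutoff frequency (Hz).
#' @return filtered data, same shape as `X`.
#' @export
filter_highpass <- function(X, fs, cutoff, order = 4) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  flt <- design_butter(order, cutoff / (fs / 2), "high")
  apply_rowwise(X, function(x) zerophase_filter(x, flt))
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
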