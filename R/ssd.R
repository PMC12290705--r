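# Spatiospectral decomposition (SSD): spatial filters maximizing power
# inside the speech-artifact frequency band against power everywhere else,
# obtained from the generalized eigenvalue problem
#   Sigma_signal w = lambda * Sigma_noise w,
# with channel-space covariances of the band-passed (signal) and
# band-stopped (noise) data. Solved by symmetric whitening of the
# ridge-regularized noise covariance followed by a symmetric eigendecomposition,
# which yields the normalization w' Sigma_noise w = 1 directly.

#' Split a recording into in-band and out-of-band parts
#'
#' `X_signal` is the zero-phase Butterworth band-pass of `X` over the
#' artifact band; `X_noise` is the band-stop complement over the same edges.
#'
#' @param X channels x samples matrix or [recording()].
#' @param band an [artifact_band()].
#' @param fs sampling rate (Hz) when `X` is a bare matrix.
#' @param order Butterworth order per pass.
#' @return list with matrices `X_signal` and `X_noise`.
#' @export
split_signal_noise <- function(X, band, fs = NULL, order = 4) {
  fs <- rec_fs(X, fs)
  Xm <- channel_matrix(X)
  stopifnot(nrow(Xm) >= 2, band$hi < fs / 2)
  list(
    X_signal = filter_bandpass(Xm, fs, band$lo, band$hi, order = order),
    X_noise = filter_bandstop(Xm, fs, band$lo, band$hi, order = order)
  )
}

#' Fit a spatiospectral decomposition
#'
#' @inheritParams split_signal_noise
#' @return an object of class `ssd_model` with `W` (channels x channels
#'   spatial filters in columns, sorted by decreasing eigenvalue), `eigvals`
#'   (in-band to out-of-band power ratios), `band`, `k` (retained dimension
#'   by the participation ratio of the eigenvalue spectrum), and `fs`.
#' @export
fit_ssd <- function(X, band, fs = NULL, order = 4) {
  fs <- rec_fs(X, fs)
  Xm <- channel_matrix(X)
  nc <- nrow(Xm)
  ns <- ncol(Xm)
  if (ns < 10 * nc)
    warning("fewer than 10 samples per channel dimension; covariance ",
            "estimates may be unstable")
  parts <- split_signal_noise(Xm, band, fs = fs, order = order)
  cs <- tcrossprod(parts$X_signal) / ns
  cn <- tcrossprod(parts$X_noise) / ns
  if (!all(is.finite(cs)) || !all(is.finite(cn)))
    stop("non-finite covariance entries")
  cn <- cn + diag(1e-6 * sum(diag(cn)) / nc, nc)  # Tikhonov ridge
  en <- eigen(cn, symmetric = TRUE)
  if (min(en$values) <= 1e-12 * max(en$values)) {
    stop("noise covariance numerically singular after ridge (rank ",
         sum(en$values > 1e-12 * max(en$values)), " of ", nc, ")")
  }
  whiten <- en$vectors %*% diag(1 / sqrt(en$values), nc)
  es <- eigen(crossprod(whiten, cs %*% whiten), symmetric = TRUE)
  W <- whiten %*% es$vectors  # columns satisfy w' cn w = 1
  # sign convention: largest-magnitude entry of each filter positive
  for (j in seq_len(nc)) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  lambda <- pmax(es$values, 0)
  structure(list(W = W, eigvals = lambda, band = band,
                 k = participation_ratio(lambda), fs = fs),
            class = "ssd_model")
}

#' Participation ratio of an eigenvalue spectrum
#'
#' Effective dimensionality `floor((sum(lambda))^2 / sum(lambda^2))`,
#' clamped to `[1, length(lambda)]`; used to select how many SSD components
#' to retain.
#'
#' @param eigvals nonnegative eigenvalues, not all zero.
#' @return integer dimension.
#' @export
participation_ratio <- function(eigvals) {
  stopifnot(all(eigvals >= 0))
  if (sum(eigvals) == 0) stop("all eigenvalues are zero")
  pr <- floor(sum(eigvals)^2 / sum(eigvals^2))
  as.integer(min(max(pr, 1), length(eigvals)))
}

#' Project a recording onto the retained SSD components
#'
#' @param X channels x samples matrix or [recording()].
#' @param model an `ssd_model`.
#' @param k number of components (default: the model's participation-ratio
#'   choice).
#' @return k x samples matrix of component time courses.
#' @export
transform_ssd <- function(X, model, k = model$k) {
  Xm <- channel_matrix(X)
  if (nrow(Xm) != nrow(model$W))
    stop("channel count (", nrow(Xm), ") does not match model (",
         nrow(model$W), ")")
  stopifnot(k >= 1, k <= ncol(model$W))
  t(model$W[, seq_len(k), drop = FALSE]) %*% Xm
}

#' @export
print.ssd_model <- function(x, ...) {
  cat(sprintf("<ssd_model> %d channels, band [%.1f, %.1f] Hz, k = %d\n",
              nrow(x$W), x$band$lo, x$band$hi, x$k))
  cat("top eigenvalues:",
      paste(signif(utils::head(x$eigvals, 5), 3), collapse = ", "), "\n")
  invisible(x)
}
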