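# Evaluation metrics: time-domain agreement (chi-squared similarity,
# max-normalized MSE), frequency-domain agreement (magnitude-squared
# coherence), phase agreement (phase-locking value), neural preservation
# (PCA-loading cosine similarity), and artifact quantification across trials
# (intertrial phase consistency and its session-level summaries).

#' Chi-squared similarity to a ground truth
#'
#' Per-channel mean squared deviation normalized by the ground-truth
#' variance: `mean((x - x_gt)^2) / var(x_gt)`.
#'
#' @param X,X_gt channels x samples matrices (or vectors) of equal shape.
#' @return per-channel nonnegative values.
#' @export
chi2_similarity <- function(X, X_gt) {
  X <- rbind(channel_matrix(X))
  X_gt <- rbind(channel_matrix(X_gt))
  stopifnot(all(dim(X) == dim(X_gt)))
  vgt <- apply(X_gt, 1, function(x) mean((x - mean(x))^2))
  if (any(vgt <= 0)) stop("zero-variance ground-truth channel")
  rowMeans((X - X_gt)^2) / vgt
}

#' Magnitude-squared coherence estimate
#'
#' Welch-based coherence `|P_ab|^2 / (P_aa * P_bb)` on the Welch frequency
#' grid; bins with zero power in either signal report 0.
#'
#' @param a,b equal-length signals.
#' @param fs sampling rate (Hz).
#' @param seg_len Welch segment length (samples), default 1 s.
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `coh` in `[0, 1]`.
#' @export
msce <- function(a, b, fs, seg_len = NULL, overlap = 0.5) {
  pab <- welch_csd(a, b, fs, seg_len = seg_len, overlap = overlap)
  paa <- Re(welch_csd(a, a, fs, seg_len = seg_len, overlap = overlap)$csd)
  pbb <- Re(welch_csd(b, b, fs, seg_len = seg_len, overlap = overlap)$csd)
  denom <- paa * pbb
  coh <- ifelse(denom > 0, Mod(pab$csd)^2 / denom, 0)
  list(freq = pab$freq, coh = pmin(coh, 1))
}

#' Phase-locking value between two signals
#'
#' Magnitude of the time-averaged unit phasor of the instantaneous phase
#' difference, `|mean(exp(i*(phi_a - phi_b)))|`, with phases from the
#' analytic signals.
#'
#' @param a,b equal-length real signals.
#' @return scalar in `[0, 1]`.
#' @export
plv <- function(a, b) {
  stopifnot(length(a) == length(b))
  ya <- analytic_vector(a)
  yb <- analytic_vector(b)
  Mod(mean(exp(1i * (Arg(ya) - Arg(yb)))))
}

#' PCA-loading cosine similarity
#'
#' Fits PCA independently to a ground-truth and a test recording and returns
#' the absolute cosine similarity between corresponding leading loading
#' vectors (sign-invariant).
#'
#' @param X_gt,X_test channels x samples matrices with equal channel count.
#' @param n_components number of leading loadings to compare.
#' @return list with `cs` (per-component values in `[0, 1]`) and `mean`.
#' @export
loading_cosine_similarity <- function(X_gt, X_test, n_components = 3) {
  X_gt <- channel_matrix(X_gt)
  X_test <- channel_matrix(X_test)
  stopifnot(nrow(X_gt) == nrow(X_test))
  if (nrow(X_gt) < n_components)
    stop("fewer channels than requested components")
  L_gt <- stats::prcomp(t(X_gt))$rotation[, seq_len(n_components), drop = FALSE]
  L_te <- stats::prcomp(t(X_test))$rotation[, seq_len(n_components), drop = FALSE]
  cs <- vapply(seq_len(n_components), function(i) {
    abs(sum(L_gt[, i] * L_te[, i])) /
      (sqrt(sum(L_gt[, i]^2)) * sqrt(sum(L_te[, i]^2)))
  }, numeric(1))
  list(cs = cs, mean = mean(cs))
}

#' Intertrial phase consistency with the audio
#'
#' For each trial the channel and the audio are band-pass filtered (default
#' 70-240 Hz, the plausible artifact range), and the normalized inner
#' product `phi_e = sum(y * z) / (||y|| * ||z||)` between the channel's
#' analytic signal `y` and the audio `z` summarizes their phase relation.
#' ITPC is `|mean(phi)| / std(phi)` across trials, with the standard
#' deviation taken as the RMS deviation of the complex `phi_e` about their
#' complex mean. Values at or above 3.08 flag a contaminated channel.
#'
#' @param trials list of [trial_epoch()] objects (equal channel counts).
#' @param band_lo,band_hi filter band (Hz); `band_hi` is clipped below
#'   Nyquist.
#' @param threshold significance threshold on ITPC.
#' @return an object of class `itpc_report`: per-channel `itpc`,
#'   `significant`, `pct_clean` (percentage of channels below threshold),
#'   `homogeneity`, `strength`.
#' @export
itpc <- function(trials, band_lo = 70, band_hi = 240, threshold = 3.08) {
  stopifnot(length(trials) >= 2)
  fs <- trials[[1]]$fs
  band_hi <- min(band_hi, 0.98 * fs / 2)
  nc <- nrow(trials[[1]]$X)
  phis <- vapply(trials, function(tr) {
    zb <- filter_bandpass(tr$audio, fs, band_lo, band_hi)
    Xb <- filter_bandpass(tr$X, fs, band_lo, band_hi)
    vapply(seq_len(nc), function(ch) {
      y <- analytic_vector(Xb[ch, ])
      sum(y * zb) / (sqrt(sum(Mod(y)^2)) * sqrt(sum(zb^2)))
    }, complex(1))
  }, complex(nc))
  phis <- rbind(phis)  # nc x n_trials
  vals <- apply(phis, 1, itpc_stat)
  summ <- artifact_summary(vals)
  structure(list(itpc = vals, significant = vals >= threshold,
                 pct_clean = 100 * mean(vals < threshold),
                 homogeneity = summ$homogeneity, strength = summ$strength,
                 threshold = threshold),
            class = "itpc_report")
}

#' ITPC statistic from per-trial complex phase values
#'
#' `|mean(phi)| / std(phi)` with the standard deviation taken as the RMS
#' deviation of the complex values about their complex mean. Identical
#' values across trials give `Inf` (zero dispersion).
#'
#' @param phis complex vector, one normalized channel-audio inner product
#'   per trial.
#' @return nonnegative scalar (possibly `Inf`).
#' @export
itpc_stat <- function(phis) {
  mu <- mean(phis)
  s <- sqrt(mean(Mod(phis - mu)^2))
  if (s == 0) return(Inf)
  Mod(mu) / s
}

#' Session-level artifact summaries from per-channel ITPC values
#'
#' Homogeneity is `1 - Nc * var(v / ||v||)`: 1 when the artifact loads all
#' channels equally and `1/Nc` for a single contaminated channel (the
#' variance of an Nc-dimensional unit vector ranges over `[0, 1/Nc]`).
#' Strength is the mean ITPC.
#'
#' @param itpc_values nonnegative per-channel ITPC values, not all zero.
#' @return list with `homogeneity` and `strength`.
#' @export
artifact_summary <- function(itpc_values) {
  v <- as.numeric(itpc_values)
  stopifnot(length(v) >= 2, all(v >= 0))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("all-zero ITPC vector")
  u <- v / nrm
  varu <- mean((u - mean(u))^2)  # population variance
  list(homogeneity = 1 - length(v) * varu, strength = mean(v))
}

#' Clean-electrode gain
#'
#' Change, in percentage points, of the fraction of channels below the ITPC
#' significance threshold after denoising: `pct_clean_after - pct_clean_before`.
#' Negative values mean the denoiser contaminated previously clean channels.
#'
#' @param itpc_before,itpc_after `itpc_report` objects (or numeric ITPC
#'   vectors) over the same channels.
#' @param threshold significance threshold used when numeric vectors are
#'   given.
#' @return percentage points.
#' @export
clean_electrode_gain <- function(itpc_before, itpc_after, threshold = 3.08) {
  pct <- function(x) {
    if (inherits(x, "itpc_report")) return(x$pct_clean)
    if (length(x) == 0) stop("empty ITPC input")
    100 * mean(x < threshold)
  }
  pct(itpc_after) - pct(itpc_before)
}

#' Max-normalized mean squared error
#'
#' Each signal is divided by its maximum absolute value before the MSE is
#' computed, bounding the error and removing scale.
#'
#' @param a,b equal-length signals with nonzero maxima.
#' @return nonnegative scalar.
#' @export
normalized_mse <- function(a, b) {
  stopifnot(length(a) == length(b))
  ma <- max(abs(a)); mb <- max(abs(b))
  if (ma == 0 || mb == 0) stop("zero-max input")
  mean((a / ma - b / mb)^2)
}

#' @export
print.itpc_report <- function(x, ...) {
  cat(sprintf(
    "<itpc_report> %d channels, %.1f%% clean (< %.2f), homogeneity %.3f, strength %.3f\n",
    length(x$itpc), x$pct_clean, x$threshold, x$homogeneity, x$strength))
  invisible(x)
}
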