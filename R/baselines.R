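# Reference denoisers the pipeline is benchmarked against: common average
# reference (CAR) as an explicit spatial filter, and the PCA+ICA low-rank
# pipeline with components scored by their phase locking to the audio.

#' Common average reference
#'
#' Subtracts the across-channel mean at every sample:
#' `X_car = (I - J/Nc) %*% X` with `J` the all-ones matrix. When `modality`
#' tags are supplied the projector is applied within each modality
#' separately.
#'
#' @param X channels x samples matrix or [recording()].
#' @param modality optional per-channel grouping tags.
#' @return re-referenced matrix, same shape.
#' @export
car <- function(X, modality = NULL) {
  Xm <- channel_matrix(X)
  if (inherits(X, "recording") && is.null(modality)) modality <- X$modality
  if (nrow(Xm) < 2) stop("CAR needs at least 2 channels")
  if (is.null(modality)) modality <- rep("all", nrow(Xm))
  out <- Xm
  for (g in unique(modality)) {
    idx <- which(modality == g)
    if (length(idx) < 2) next
    out[idx, ] <- sweep(Xm[idx, , drop = FALSE], 2,
                        colMeans(Xm[idx, , drop = FALSE]))
  }
  out
}

#' CAR projector matrix
#'
#' @param nc number of channels.
#' @return the `nc x nc` matrix `I - J/nc`.
#' @export
car_matrix <- function(nc) {
  stopifnot(nc >= 2)
  diag(nc) - matrix(1 / nc, nc, nc)
}

# Deterministic maximum-likelihood ICA: symmetric fixed-point iteration with
# the logcosh nonlinearity on whitened data. Input must already be whitened
# (unit covariance). Returns the orthogonal unmixing matrix (components in
# rows of W %*% X).
ml_ica <- function(Xw, seed = 1, max_iter = 500, tol = 1e-7) {
  k <- nrow(Xw)
  ns <- ncol(Xw)
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k))
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% Xw
    g <- tanh(WX)
    gp <- 1 - g^2
    W_new <- sym_orth(g %*% t(Xw) / ns - diag(rowMeans(gp)) %*% W)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, iterations = it)
}

#' PCA+ICA denoising with audio-phase component scoring
#'
#' High-passes above 2 Hz, z-scores each channel, reduces with PCA at 99%
#' explained variance, runs a deterministic maximum-likelihood ICA on the
#' whitened scores, ranks components by their phase-locking value with the
#' audio's analytic phase inside the artifact band, removes the top
#' components (same elbow rule as the PCD pipeline), and reconstructs back
#' to channel space on the original scale.
#'
#' @param X channels x samples matrix or [recording()].
#' @param audio aligned audio waveform.
#' @param band an [artifact_band()]; estimated from the audio when `NULL`.
#' @param fs sampling rate (Hz) when `X` is a bare matrix.
#' @param var_explained PCA variance retention threshold.
#' @param m fixed number of components to remove (`NULL`: elbow rule on the
#'   sorted PLVs).
#' @param seed integer seed for the ICA initialization.
#' @param max_iter,tol ICA iteration cap and convergence tolerance; a
#'   non-converged fit is used as-is and flagged in the report.
#' @return list with `X_denoised` and `report` (a [tibble::tibble()] of
#'   per-component PLVs and removal flags, plus attributes `removed`,
#'   `converged`).
#' @export
ica_denoise <- function(X, audio, band = NULL, fs = NULL,
                        var_explained = 0.99, m = NULL, seed = 1,
                        max_iter = 500, tol = 1e-7) {
  fs <- rec_fs(X, fs)
  Xm <- channel_matrix(X)
  if (nrow(Xm) < 3) stop("PCA+ICA needs at least 3 channels")
  stopifnot(length(audio) == ncol(Xm))
  if (is.null(band)) band <- estimate_safband(audio, fs)
  Xh <- filter_highpass(Xm, fs, 2, order = 4)
  mu <- rowMeans(Xh)
  sdv <- apply(Xh, 1, stats::sd)
  Xz <- (Xh - mu) / sdv
  pc <- stats::prcomp(t(Xz), center = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  npc <- max(2L, which(cum >= var_explained)[1])
  scores <- t(pc$x[, seq_len(npc), drop = FALSE])   # npc x ns
  white <- scores / pc$sdev[seq_len(npc)]
  ica <- ml_ica(white, seed = seed, max_iter = max_iter, tol = tol)
  if (!ica$converged)
    warning("ICA did not converge in ", max_iter,
            " iterations; using best iterate")
  S <- ica$W %*% white                               # npc x ns sources
  # score components by phase locking with the audio inside the band
  z_band <- filter_bandpass(audio, fs, band$lo, band$hi)
  plvs <- apply(S, 1, function(s) {
    plv(filter_bandpass(s, fs, band$lo, band$hi), z_band)
  })
  ord <- order(plvs, decreasing = TRUE)
  removed <- if (!is.null(m) && m == 0) {
    integer(0)
  } else {
    sel <- if (is.null(m)) select_artifact_components(plvs[ord])
           else select_artifact_components(plvs[ord], method = "fixed", m = m)
    ord[seq_len(sel$m)]
  }
  # invert: sources -> whitened scores -> scores -> z-scored channels
  S_clean <- S
  S_clean[removed, ] <- 0
  white_clean <- t(ica$W) %*% S_clean
  scores_clean <- white_clean * pc$sdev[seq_len(npc)]
  Xz_clean <- pc$rotation[, seq_len(npc), drop = FALSE] %*% scores_clean
  X_out <- Xz_clean * sdv + mu
  report <- tibble::tibble(
    component = seq_len(npc),
    plv = plvs,
    removed = seq_len(npc) %in% removed
  )
  attr(report, "removed") <- removed
  attr(report, "converged") <- ica$converged
  attr(report, "n_pca") <- npc
  list(X_denoised = X_out, report = report)
}
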