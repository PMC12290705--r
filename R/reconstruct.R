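# Composition of the full phase-coupling decomposition (PCD) model and the
# trial-wise denoising pipeline: estimate the artifact band from the audio,
# preprocess, fit SSD, fit PCO in the whitened SSD space, pick the number of
# artifactual components at the elbow of the MVL trace, compose the
# unmixing/mixing pair, and reconstruct the wide epoch with the artifactual
# components zeroed out.

block_diag <- function(A, B) {
  if (is.null(dim(A))) A <- as.matrix(A)
  if (is.null(dim(B))) B <- as.matrix(B)
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

#' Compose the PCD unmixing matrix
#'
#' Embeds the whitened k-dimensional PCO solution into channel space:
#' the first SSD components pass through the whitening matrix and the PCO
#' filters, the remaining channel dimensions pass through unchanged, so that
#' `t(W_pcd) %*% X` reproduces the sequential SSD -> whiten -> PCO path.
#'
#' @param M_white whitening matrix (rank x k) used by the PCO fit.
#' @param W_ssd channels x channels SSD filter matrix.
#' @param W_pco PCO filter matrix (rank x rank) in the whitened space.
#' @param k number of SSD components the PCO stage consumed.
#' @return channels x (rank + channels - k) unmixing matrix, artifact
#'   components first.
#' @export
compose_unmixing <- function(M_white, W_ssd, W_pco, k) {
  M_white <- as.matrix(M_white)
  nc <- nrow(W_ssd)
  r <- nrow(M_white)
  stopifnot(ncol(M_white) == k, k <= nc,
            nrow(W_pco) == r, ncol(W_pco) == r)
  rest <- nc - k
  M_emb <- if (rest > 0) block_diag(M_white, diag(rest)) else M_white
  P_emb <- if (rest > 0) block_diag(W_pco, diag(rest)) else W_pco
  W_ssd %*% t(M_emb) %*% P_emb
}

#' Mixing matrix from an unmixing matrix
#'
#' The Moore-Penrose pseudoinverse companion of the unmixing matrix, chosen
#' so that the forward/backward pair `X = A %*% S`, `S = t(W) %*% X` is
#' consistent: `A = pinv(t(W))`.
#'
#' @param W_pcd unmixing matrix (channels x components).
#' @return mixing matrix of the same shape.
#' @export
mixing_from_unmixing <- function(W_pcd) {
  stopifnot(all(is.finite(W_pcd)))
  t(MASS::ginv(W_pcd))
}

#' Low-rank artifact rejection
#'
#' Reconstructs the data with the `m` top-MVL (artifactual) components
#' removed: `X_denoised = A[, -(1:m)] %*% t(W[, -(1:m)]) %*% X`.
#'
#' @param X channels x samples matrix or [recording()].
#' @param model a `pcd_model` (or any list with `W_pcd`, `A_pcd`,
#'   `selection`).
#' @param m number of leading components to remove; defaults to the model's
#'   selection. `m = 0` reproduces `X` (up to the rank retained by the
#'   factorization).
#' @return denoised channels x samples matrix.
#' @export
denoise <- function(X, model, m = model$selection$m) {
  Xm <- channel_matrix(X)
  q <- ncol(model$W_pcd)
  if (m >= q) stop("m = ", m, " would remove all ", q, " components")
  keep <- if (m == 0) seq_len(q) else setdiff(seq_len(q), seq_len(m))
  model$A_pcd[, keep, drop = FALSE] %*%
    (t(model$W_pcd[, keep, drop = FALSE]) %*% Xm)
}

#' Standard preprocessing for intracranial recordings
#'
#' Zero-phase high-pass above 2 Hz and zero-phase notches at the 60 Hz line
#' frequency and its first three harmonics (120, 180, 240 Hz). Notches at or
#' above Nyquist are skipped with a message.
#'
#' @param X channels x samples matrix or [recording()].
#' @param fs sampling rate (Hz) when `X` is a bare matrix.
#' @param line_hz line frequency (Hz).
#' @param notch_halfwidth half-width of each notch (Hz).
#' @return preprocessed matrix, same shape.
#' @export
preprocess <- function(X, fs = NULL, line_hz = 60, notch_halfwidth = 2) {
  fs <- rec_fs(X, fs)
  Xm <- channel_matrix(X)
  Xm <- filter_highpass(Xm, fs, 2, order = 4)
  for (f0 in line_hz * 1:4) {
    if (f0 + notch_halfwidth >= fs / 2) {
      message("skipping notch at ", f0, " Hz (at or above Nyquist)")
      next
    }
    Xm <- filter_bandstop(Xm, fs, f0 - notch_halfwidth,
                          f0 + notch_halfwidth, order = 2)
  }
  Xm
}

#' PCD configuration
#'
#' @param fit_window c(start, end) of the model-fitting epoch, seconds
#'   relative to the produced-speech onset.
#' @param wide_window c(start, end) of the application epoch, seconds
#'   relative to onset (clipped at the recording edges).
#' @param n_restarts PCO random restarts.
#' @param seed integer seed.
#' @param ssd_order Butterworth order for the SSD band filters.
#' @param do_preprocess apply [preprocess()] before fitting.
#' @param elbow_m fixed number of components to remove (`NULL`: automatic
#'   elbow selection).
#' @param f0_search search band for the voice fundamental (Hz).
#' @return configuration list of class `pcd_config`.
#' @export
pcd_config <- function(fit_window = c(-0.5, 2), wide_window = c(-6, 6),
                       n_restarts = 10, seed = 1, ssd_order = 4,
                       do_preprocess = TRUE, elbow_m = NULL,
                       f0_search = c(50, 250)) {
  stopifnot(fit_window[1] < fit_window[2], wide_window[1] < wide_window[2])
  structure(list(fit_window = fit_window, wide_window = wide_window,
                 n_restarts = n_restarts, seed = as.integer(seed),
                 ssd_order = ssd_order, do_preprocess = do_preprocess,
                 elbow_m = elbow_m, f0_search = f0_search),
            class = "pcd_config")
}

window_indices <- function(onset, win, fs, n) {
  idx <- (onset + round(win[1] * fs)):(onset + round(win[2] * fs))
  idx[idx >= 1 & idx <= n]
}

#' Run the full PCD pipeline on one trial
#'
#' Estimates the speech-artifact band from the audio of the fit epoch,
#' preprocesses the recording, fits SSD (dimension chosen by the
#' participation ratio), fits PCO on the analytic SSD projection against the
#' z-scored audio, selects the artifactual components at the MVL elbow,
#' composes the PCD unmixing/mixing pair, and applies the low-rank
#' reconstruction to the wide epoch.
#'
#' @param trial a [trial_epoch()]. All recording modalities are treated as a
#'   single sensor space (one stacked channel dimension).
#' @param cfg a [pcd_config()].
#' @return list with `X_denoised` (channels x wide-epoch samples), `model`
#'   (class `pcd_model`), `artifact_sources` (m x wide-epoch estimated
#'   artifact time courses), and `wide_index` (sample indices of the wide
#'   epoch in the trial).
#' @export
run_pcd_trial <- function(trial, cfg = pcd_config()) {
  stopifnot(inherits(trial, "trial_epoch"))
  if (nrow(trial$X) < 3) stop("PCD needs at least 3 channels")
  fs <- trial$fs
  n <- ncol(trial$X)
  fit_idx <- window_indices(trial$onset_index, cfg$fit_window, fs, n)
  wide_idx <- window_indices(trial$onset_index, cfg$wide_window, fs, n)
  audio_fit <- trial$audio[fit_idx]
  band <- estimate_safband(audio_fit, fs,
                           f0_hint = estimate_f0(audio_fit, fs,
                                                 cfg$f0_search[1],
                                                 cfg$f0_search[2]))
  Xp <- if (cfg$do_preprocess) preprocess(trial$X, fs) else trial$X
  ssd <- fit_ssd(Xp[, fit_idx, drop = FALSE], band, fs = fs,
                 order = cfg$ssd_order)
  k <- ssd$k
  z_fit <- (audio_fit - mean(audio_fit)) / stats::sd(audio_fit)
  Y <- analytic_signal(transform_ssd(Xp[, fit_idx, drop = FALSE], ssd, k))
  pco <- fit_pco(Y, z_fit, n_restarts = cfg$n_restarts, seed = cfg$seed)
  sel <- if (is.null(cfg$elbow_m)) {
    select_artifact_components(pco$mvls)
  } else {
    select_artifact_components(pco$mvls, method = "fixed", m = cfg$elbow_m)
  }
  W_pcd <- compose_unmixing(pco$M_white, ssd$W, pco$W, k)
  A_pcd <- mixing_from_unmixing(W_pcd)
  model <- structure(list(W_pcd = W_pcd, A_pcd = A_pcd, ssd = ssd,
                          pco = pco, selection = sel, band = band,
                          fit_window = cfg$fit_window, fs = fs),
                     class = "pcd_model")
  X_wide <- Xp[, wide_idx, drop = FALSE]
  X_den <- denoise(X_wide, model)
  S_hat <- t(W_pcd[, seq_len(sel$m), drop = FALSE]) %*% X_wide
  list(X_denoised = X_den, model = model, artifact_sources = S_hat,
       wide_index = wide_idx)
}

#' @export
print.pcd_model <- function(x, ...) {
  cat(sprintf(
    "<pcd_model> %d channels, band [%.1f, %.1f] Hz, k = %d, m = %d (%s)\n",
    nrow(x$W_pcd), x$band$lo, x$band$hi, x$ssd$k, x$selection$m,
    x$selection$method))
  cat("component MVL:", paste(signif(x$pco$mvls, 3), collapse = ", "), "\n")
  invisible(x)
}
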