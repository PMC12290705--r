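# Model composition, low-rank reconstruction, preprocessing, and the
# end-to-end trial pipeline.

test_that("neutral PCO and whitening blocks leave the SSD filters unchanged", {
  W_ssd <- withr::with_seed(1, matrix(stats::rnorm(25), 5))
  W <- compose_unmixing(diag(3), W_ssd, diag(3), k = 3)
  expect_equal(W, W_ssd)
})

test_that("the composed unmixing is path-equivalent to the sequential transform", {
  sim <- small_trial(seed = 2, agr_db = 2)
  res <- run_pcd_trial(sim$trial, fast_cfg(seed = 2))
  model <- res$model
  Xp <- preprocess(sim$trial$X, 1000)
  fit_idx <- pcdenoise:::window_indices(sim$trial$onset_index,
                                        model$fit_window, 1000,
                                        ncol(Xp))
  Xw <- Xp[, fit_idx]
  seq_path <- Re(t(model$pco$W) %*%
                   (model$pco$M_white %*%
                      transform_ssd(Xw, model$ssd, model$ssd$k)))
  comp_path <- t(model$W_pcd[, seq_len(model$ssd$k), drop = FALSE]) %*% Xw
  rel <- norm(comp_path - seq_path, "F") / norm(seq_path, "F")
  expect_lt(rel, 1e-6)
})

test_that("consistently permuting channels permutes the unmixing rows", {
  W_ssd <- withr::with_seed(3, matrix(stats::rnorm(16), 4))
  M <- withr::with_seed(4, matrix(stats::rnorm(4), 2))
  W_pco <- withr::with_seed(5, matrix(stats::rnorm(4), 2))
  W <- compose_unmixing(M, W_ssd, W_pco, k = 2)
  perm <- c(2, 4, 1, 3)
  W_perm <- compose_unmixing(M, W_ssd[perm, ], W_pco, k = 2)
  expect_equal(W_perm, W[perm, ])
})

test_that("the mixing matrix is the pseudoinverse companion of the unmixing", {
  Q <- qr.Q(qr(withr::with_seed(6, matrix(stats::rnorm(16), 4))))
  expect_equal(mixing_from_unmixing(Q), Q, tolerance = 1e-10)
  W <- withr::with_seed(7, matrix(stats::rnorm(36), 6)) + diag(6)
  A <- mixing_from_unmixing(W)
  X <- withr::with_seed(8, matrix(stats::rnorm(6 * 50), 6))
  expect_equal(A %*% (t(W) %*% X), X, tolerance = 1e-8)
  # rank-deficient: round trip lands on the row-space projection
  Wr <- W
  Wr[, 6] <- Wr[, 5]
  Ar <- mixing_from_unmixing(Wr)
  P <- Ar %*% t(Wr)
  expect_equal(P %*% P, P, tolerance = 1e-6)          # projector
  expect_lt(norm(P - diag(6), "F") / norm(diag(6), "F"), 1)
})

test_that("removing zero components reproduces the input; removing all is rejected", {
  W <- withr::with_seed(9, matrix(stats::rnorm(25), 5)) + diag(5)
  model <- list(W_pcd = W, A_pcd = mixing_from_unmixing(W),
                selection = list(m = 0))
  X <- withr::with_seed(10, matrix(stats::rnorm(5 * 100), 5))
  expect_equal(denoise(X, model), X, tolerance = 1e-8)
  expect_error(denoise(X, model, m = 5), "all")
  Xd <- denoise(X, model, m = 4)
  expect_equal(qr(Xd)$rank, 1)
})

test_that("denoising drops in-band power without touching low frequencies", {
  sim <- small_trial(seed = 11, nc = 16, agr_db = 15, duration = 3)
  # add low-frequency neural background so the 10-50 Hz band carries real
  # signal (the gamma sources are band-limited to 60-200 Hz)
  low <- withr::with_seed(111, {
    mixing <- matrix(stats::rnorm(16 * 4), 16)
    src <- matrix(stats::rnorm(4 * 3000), 4)
    mixing %*% filter_bandpass(src, 1000, 5, 45, order = 4)
  })
  low <- low * stats::sd(sim$X_clean) / stats::sd(low)
  trial <- trial_epoch(sim$trial$X + low, sim$trial$audio,
                       sim$trial$onset_index, fs = 1000)
  res <- run_pcd_trial(trial, fast_cfg(seed = 11))
  Xp <- preprocess(trial$X, 1000)[, res$wide_index]
  band <- res$model$band
  bp <- function(X, lo, hi) {
    mean(apply(rbind(X), 1, band_power, fs = 1000, lo = lo, hi = hi))
  }
  drop_in <- 10 * log10(bp(Xp, band$lo, band$hi) /
                          bp(res$X_denoised, band$lo, band$hi))
  change_out <- abs(10 * log10(bp(Xp, 10, 50) /
                                 bp(res$X_denoised, 10, 50)))
  expect_gte(drop_in, 10)
  expect_lt(change_out, 1)
})

test_that("preprocessing removes DC and line noise but preserves the passband", {
  fs <- 1000; tt <- (0:2999) / fs
  x_dc <- rbind(rep(0, 3000) + 5 + 0.1 * sin(2 * pi * 30 * tt))
  expect_lt(abs(mean(preprocess(x_dc, fs))), 5e-3)
  core <- 300:2700  # steady state, away from filter edge transients
  x60 <- rbind(sin(2 * pi * 60 * tt))
  expect_lt(sqrt(mean(preprocess(x60, fs)[core]^2)) / sqrt(mean(x60^2)),
            0.05)
  x100 <- rbind(sin(2 * pi * 100 * tt))
  expect_equal(sqrt(mean(preprocess(x100, fs)[core]^2)),
               sqrt(mean(x100[core]^2)), tolerance = 0.05)
})

test_that("notches above Nyquist are skipped rather than fatal", {
  x <- rbind(withr::with_seed(12, stats::rnorm(1000)))
  expect_message(preprocess(x, fs = 300), "skipping notch")
})

test_that("PCD reduces the fraction of audio-coupled channels across trials", {
  # fixed mixing across trials: a stable acquisition chain gives the
  # artifact a consistent phase relation, which is what ITPC detects
  sims <- lapply(1:10, function(i) small_trial(seed = 300 + i, nc = 8,
                                               agr_db = 5, duration = 3,
                                               mix_seed = 299))
  raw_trials <- lapply(sims, `[[`, "trial")
  den_trials <- lapply(sims, function(sm) {
    res <- run_pcd_trial(sm$trial, fast_cfg(seed = sm$trial$onset_index))
    trial_epoch(res$X_denoised, sm$trial$audio[res$wide_index],
                sm$trial$onset_index, fs = 1000)
  })
  rep_raw <- itpc(raw_trials)
  rep_den <- itpc(den_trials)
  expect_lt(mean(rep_den$significant), mean(rep_raw$significant))
  expect_gte(clean_electrode_gain(rep_raw, rep_den), 0)
})

test_that("an artifact-free trial passes through nearly untouched", {
  sim <- small_trial(seed = 13, nc = 12, agr_db = -60, duration = 3)
  res <- run_pcd_trial(sim$trial, fast_cfg(seed = 13))
  cs <- loading_cosine_similarity(sim$X_clean[, res$wide_index],
                                  res$X_denoised)
  expect_gte(cs$mean, 0.95)
})

test_that("the pipeline is deterministic given configuration and seed", {
  sim <- small_trial(seed = 14)
  r1 <- run_pcd_trial(sim$trial, fast_cfg(seed = 14))
  r2 <- run_pcd_trial(sim$trial, fast_cfg(seed = 14))
  expect_identical(r1$X_denoised, r2$X_denoised)
  expect_identical(r1$model$W_pcd, r2$model$W_pcd)
})

test_that("flipping the audio sign leaves the denoised output unchanged", {
  sim <- small_trial(seed = 15)
  trial_flip <- trial_epoch(sim$trial$X, -sim$trial$audio,
                            sim$trial$onset_index, fs = 1000)
  r1 <- run_pcd_trial(sim$trial, fast_cfg(seed = 15))
  r2 <- run_pcd_trial(trial_flip, fast_cfg(seed = 15))
  expect_equal(r1$X_denoised, r2$X_denoised, tolerance = 1e-9)
})

test_that("denoising does not inflate channel variance on mixed single-artifact data", {
  n_dec <- 0; n_tot <- 0
  for (i in 1:20) {
    sim <- small_trial(seed = 400 + i, nc = 16, agr_db = 0)
    res <- run_pcd_trial(sim$trial, fast_cfg(seed = 400 + i))
    Xp <- preprocess(sim$trial$X, 1000)[, res$wide_index]
    v_before <- apply(Xp, 1, stats::var)
    v_after <- apply(res$X_denoised, 1, stats::var)
    n_dec <- n_dec + sum(v_after <= v_before * (1 + 1e-9))
    n_tot <- n_tot + length(v_before)
  }
  expect_gte(n_dec / n_tot, 0.9)
})
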