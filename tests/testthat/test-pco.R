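# Analytic signal, mean vector length, and the phase-coupling optimizer.

test_that("the analytic signal has the expected quadrature and envelope", {
  fs <- 1000; tt <- (0:1999) / fs
  y <- analytic_signal(cos(2 * pi * 50 * tt))
  core <- 100:1900
  expect_lt(max(abs(Re(y[core]) - cos(2 * pi * 50 * tt)[core])), 1e-9)
  expect_lt(max(abs(Im(y[core]) - sin(2 * pi * 50 * tt)[core])), 1e-3)
  # DC has no quadrature
  expect_lt(max(abs(Im(analytic_signal(rep(2, 100))))), 1e-6)
  # slow AM envelope is recovered
  a_t <- 1 + 0.5 * sin(2 * pi * 2 * tt)
  y2 <- analytic_signal(a_t * cos(2 * pi * 100 * tt))
  rel_rms <- sqrt(mean((Mod(y2[core]) - a_t[core])^2)) /
    sqrt(mean(a_t[core]^2))
  expect_lt(rel_rms, 0.05)
  # rowwise operation matches vector operation
  X <- rbind(cos(2 * pi * 10 * tt), sin(2 * pi * 30 * tt))
  Y <- analytic_signal(X)
  expect_equal(Y[1, ], analytic_signal(X[1, ]))
})

test_that("the mean vector length matches its closed forms", {
  fs <- 1000; tt <- (0:9999) / fs
  Y <- rbind(exp(2i * pi * 40 * tt))
  expect_equal(mvl(1, Y, rep(0, length(tt))), 0)
  z <- sqrt(2) * cos(2 * pi * 40 * tt)  # z-scored cosine
  expect_equal(mvl(1, Y, z), sqrt(2) / 2, tolerance = 0.01)
  expect_error(mvl(1, rbind(complex(real = rep(0, 100))), rep(1, 100)),
               "all-zero")
})

test_that("the MVL of an unrelated target stays at the noise floor", {
  fs <- 1000; tt <- (0:9999) / fs
  Y <- rbind(exp(2i * pi * 40 * tt))
  vals <- vapply(1:100, function(i) {
    z <- withr::with_seed(200 + i, as.vector(scale(stats::rnorm(10000))))
    mvl(1, Y, z)
  }, numeric(1))
  expect_gte(mean(vals < 0.05), 0.95)
})

test_that("the analytic MVL gradient matches finite differences", {
  fs <- 500; n <- 600
  Y <- analytic_signal(withr::with_seed(1, matrix(stats::rnorm(3 * n), 3)))
  z <- withr::with_seed(2, as.vector(scale(stats::rnorm(n))))
  w <- c(0.5, -1, 0.25)
  g <- pcdenoise:::mvl_grad(w, Y, z)
  num <- vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- 1e-6
    (mvl(w + e, Y, z) - mvl(w - e, Y, z)) / 2e-6
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("PCO pulls out a planted artifact direction with near-unit phase locking", {
  fs <- 1000; dur <- 2.5; n <- dur * fs
  art <- gen_audio(audio_params("cas", f0 = 150, df = 8, duration = dur,
                                fs = fs, seed = 31))$wave
  S <- rbind(art,
             t(vapply(1:3, function(i) {
               gen_gamma_source(gamma_params(seed = 40 + i, mu = 1.2), dur, fs)
             }, numeric(n))))
  A <- withr::with_seed(32, matrix(stats::rnorm(16), 4))
  X <- A %*% S
  Y <- analytic_signal(X)
  z <- as.vector(scale(art))
  m <- fit_pco(Y, z, n_restarts = 6, seed = 33)
  s_hat <- Re(as.vector(m$W[, 1] %*% (m$M_white %*% Y)))
  expect_gte(plv(s_hat, art), 0.99)
  # phase difference concentrates at 0 or pi
  dphi <- Arg(mean(exp(1i * (Arg(analytic_signal(s_hat)) -
                               Arg(analytic_signal(art))))))
  folded <- min(abs(dphi), pi - abs(dphi))
  expect_lt(folded, 0.1)
})

test_that("PCO against unrelated audio stays below a circular-shift null", {
  fs <- 1000; n <- 2000
  X <- withr::with_seed(51, matrix(stats::rnorm(3 * n), 3))
  Y <- analytic_signal(X)
  z <- withr::with_seed(52, as.vector(scale(stats::rnorm(n))))
  m <- fit_pco(Y, z, n_restarts = 4, seed = 53)
  null <- vapply(1:50, function(i) {
    shift <- withr::with_seed(60 + i, sample.int(n, 1))
    zs <- c(z[-seq_len(shift)], z[seq_len(shift)])
    fit_pco(Y, zs, n_restarts = 2, seed = 54)$mvls[1]
  }, numeric(1))
  expect_lte(m$mvls[1], stats::quantile(null, 0.95) * 1.15)
})

test_that("the PCO fit is deterministic given the seed", {
  fs <- 1000; n <- 1500
  X <- withr::with_seed(61, matrix(stats::rnorm(3 * n), 3))
  Y <- analytic_signal(X)
  z <- withr::with_seed(62, as.vector(scale(stats::rnorm(n))))
  m1 <- fit_pco(Y, z, n_restarts = 3, seed = 63)
  m2 <- fit_pco(Y, z, n_restarts = 3, seed = 63)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$mvls, m2$mvls)
})

test_that("reported component MVLs dominate their random initializations", {
  fs <- 1000; n <- 1500
  sim <- small_trial(seed = 71, nc = 6)
  band <- artifact_band(150, 10)
  ssd <- fit_ssd(sim$trial$X, band, fs = 1000)
  Y <- analytic_signal(transform_ssd(sim$trial$X, ssd, k = 3))
  z <- as.vector(scale(sim$trial$audio))
  m <- fit_pco(Y, z, n_restarts = 4, seed = 72)
  Yw <- m$M_white %*% Y
  inits <- withr::with_seed(72, matrix(stats::rnorm(3 * 4), ncol = 4))
  for (j in 1:4) {
    w0 <- inits[, j] / sqrt(sum(inits[, j]^2))
    expect_gte(m$mvls[1] + 1e-10, mvl(w0, Yw, z))
  }
})

test_that("deflated components are mutually uncorrelated in the whitened space", {
  sim <- small_trial(seed = 81, nc = 8, agr_db = 3)
  band <- artifact_band(150, 10)
  ssd <- fit_ssd(sim$trial$X, band, fs = 1000)
  Y <- analytic_signal(transform_ssd(sim$trial$X, ssd, k = 4))
  z <- as.vector(scale(sim$trial$audio))
  m <- fit_pco(Y, z, n_restarts = 3, seed = 82)
  S <- Re(t(m$W) %*% (m$M_white %*% Y))
  cc <- stats::cor(t(S))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-3)
})

test_that("at k = 2 the optimizer matches an exhaustive angle scan", {
  fs <- 1000; n <- 2000
  art <- gen_audio(audio_params("cas", duration = 2, fs = fs, seed = 91))$wave
  S <- rbind(art, gen_gamma_source(gamma_params(seed = 92, mu = 1), 2, fs))
  A <- withr::with_seed(93, matrix(stats::rnorm(4), 2))
  Y <- analytic_signal(A %*% S)
  z <- as.vector(scale(art))
  m <- fit_pco(Y, z, n_restarts = 5, seed = 94)
  Yw <- m$M_white %*% Y
  angles <- seq(0, pi, length.out = 3600)
  scan <- vapply(angles, function(a) mvl(c(cos(a), sin(a)), Yw, z),
                 numeric(1))
  expect_equal(m$mvls[1], max(scan), tolerance = 0.01)
})

test_that("the MVL elbow rule selects the curvature break", {
  expect_identical(select_artifact_components(c(0.9, 0.1, 0.09, 0.08))$m, 1L)
  expect_identical(select_artifact_components(c(0.9, 0.85, 0.1, 0.09))$m, 2L)
  expect_identical(select_artifact_components(c(0.5, 0.2))$m, 1L)
  expect_identical(select_artifact_components(0.4)$m, 1L)
  sel <- select_artifact_components(c(0.9, 0.8, 0.7), method = "fixed", m = 2)
  expect_identical(sel$m, 2L)
  expect_identical(sel$method, "fixed")
})
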