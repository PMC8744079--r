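# shared calibration material for the design tests
white_mics <- local({
  set.seed(42)
  n <- FS * 4
  w4 <- lapply(1:4, function(i) wave_mono(stats::rnorm(n, 0, 0.1), FS))
  mic_frame(w4[[1]], w4[[2]], w4[[3]], w4[[4]])
})

test_that("noise covariance of spatially white noise is ~ sigma^2 I", {
  set.seed(13)
  n <- FS * 10
  mk <- function() wave_mono(stats::rnorm(n, 0, 0.1), FS)
  mics <- mic_frame(mk(), mk(), mk(), mk())
  R <- estimate_noise_covariance(mics, CFG)
  sigma2 <- 0.1 ^ 2 * sum(hearsim:::sqrt_hann_window(256) ^ 2)
  for (k in c(10, 40, 64, 100)) {
    Rk <- R$R[, , k]
    expect_lt(max(abs(Re(diag(Rk)) - sigma2)) / sigma2, 0.1)
    off <- Rk - diag(Re(diag(Rk)))
    expect_lt(max(Mod(off)) / sigma2, 0.1)
    expect_lt(max(Mod(Rk - Conj(t(Rk)))), 1e-12)
  }

  # quadratic amplitude scaling
  mics2 <- hearsim:::mic_scale(mics, 2)
  R2 <- estimate_noise_covariance(mics2, CFG)
  tr1 <- Re(sum(diag(R$R[, , 40])))
  tr2 <- Re(sum(diag(R2$R[, , 40])))
  expect_equal(tr2 / tr1, 4, tolerance = 1e-3)

  expect_error(estimate_noise_covariance(
    mic_frame(wave_mono(rnorm(600), FS), wave_mono(rnorm(600), FS),
              wave_mono(rnorm(600), FS), wave_mono(rnorm(600), FS)), CFG),
    "too short")
})

test_that("a point source yields a rank-1 dominated covariance", {
  # single source, per-mic gains and acoustic-scale (few-sample) delays
  src <- wgn_wave(FS * 5, seed = 4)$samples
  shift <- function(x, d) c(rep(0, d), x[seq_len(length(x) - d)])
  mics <- mic_frame(wave_mono(src, FS),
                    wave_mono(0.8 * shift(src, 1), FS),
                    wave_mono(0.9 * shift(src, 2), FS),
                    wave_mono(0.7 * shift(src, 4), FS))
  R <- estimate_noise_covariance(mics, CFG, loading = 0)
  for (k in c(20, 60, 100)) {
    ev <- eigen(R$R[, , k], symmetric = TRUE, only.values = TRUE)$values
    expect_gt(ev[1] / sum(ev), 0.95)
  }
})

test_that("steering vectors recover relative transfer functions", {
  # identical signal on all mics -> d = (1,1,1,1)
  x <- wgn_wave(FS * 2, seed = 5)
  same <- mic_frame(x, x, x, x)
  d <- estimate_steering_vector(same, "lf", CFG)
  expect_lt(max(Mod(d$d - 1)), 1e-10)
  expect_true(all(d$d[1, ] == 1 + 0i))

  # pure acoustic-scale delay on LB vs LF: d_LB = exp(-i w tau).  The
  # windowed-frame estimate degrades as the delay grows towards the hop
  # size, so the oracle is checked at a realistic 4-sample (0.25 ms) delay.
  D <- 4
  xd <- wave_mono(c(rep(0, D), x$samples[1:(FS * 2 - D)]), FS)
  mics <- mic_frame(x, xd, x, x)
  d2 <- estimate_steering_vector(mics, "lf", CFG)
  k <- 2:120
  omega <- 2 * pi * (k - 1) / 256
  expected <- exp(-1i * omega * D)
  expect_lt(max(Mod(d2$d[2, k] - expected)), 0.02)
  expect_true(all(d2$d[1, ] == 1 + 0i))
})

test_that("MVDR weights satisfy the constraint and minimise noise power", {
  geom <- bte_array_geometry()
  src <- make_noise("ssn", synth_utterance(2, seed = 6)$wave, 5, seed = 7)
  target <- render_scene(src, simulate_brirs(geom, 0, 1.5, fs = FS))
  d <- estimate_steering_vector(target, "lf", CFG)
  R <- estimate_noise_covariance(white_mics, CFG)
  w <- design_mvdr(d, R)

  # distortionless constraint exact per bin
  dev <- abs(colSums(Conj(w) * d$d) - 1)
  expect_lt(max(dev), 1e-12)

  # noise power never above the reference-mic pass-through
  e_ref <- c(1, 0, 0, 0)
  for (k in seq_len(129)) {
    p_w <- Re(Conj(w[, k]) %*% R$R[, , k] %*% w[, k])
    p_ref <- Re(e_ref %*% R$R[, , k] %*% e_ref)
    expect_lte(as.numeric(p_w), as.numeric(p_ref) * (1 + 1e-10))
  }

  # R = I gives the matched filter d / (d^H d)
  Rid <- R
  for (k in seq_len(129)) Rid$R[, , k] <- diag(4) + 0i
  wm <- design_mvdr(d, Rid)
  expected <- sapply(seq_len(129), function(k)
    d$d[, k] / sum(Mod(d$d[, k]) ^ 2))
  expect_lt(max(Mod(wm - expected)), 1e-10)
})

test_that("beamformer configurations wire the outputs as specified", {
  geom <- bte_array_geometry()
  utt <- synth_utterance(2, seed = 8)$wave
  irs <- simulate_brirs(geom, 0, 1.5, fs = FS)
  cal_t <- render_scene(utt, irs)
  scene <- scene_spec(0, 60, seed = 2)
  nz <- make_noise("ssn", utt, 6, seed = 9)
  cal_n <- render_scene(nz, simulate_brirs(geom, 60, 1.5, fs = FS, seed = 2))

  des_none <- design_beamformer(cal_t, cal_n, "none")
  mix <- cal_t
  b <- apply_beamforming(mix, des_none)
  expect_identical(b$L$values, stft(mix$lf, CFG)$values)
  expect_identical(b$R$values, stft(mix$rf, CFG)$values)

  des_bn <- design_beamformer(cal_t, cal_n, "bn")
  b2 <- apply_beamforming(mix, des_bn)
  expect_identical(b2$M$values, b2$L$values)

  des_bl <- design_beamformer(cal_t, cal_n, "bl")
  b3 <- apply_beamforming(mix, des_bl)
  expect_false(isTRUE(all.equal(b3$M$values, b3$L$values)))

  # distortionless pass-through of the calibrated target: L ~ LF clean
  y <- istft(b2$L)
  ref <- mix$lf$samples
  err_db <- 10 * log10(sum((y$samples - ref) ^ 2) / sum(ref ^ 2))
  expect_lt(err_db, -40)
})

test_that("weights are invariant to the calibration gain", {
  geom <- bte_array_geometry()
  utt <- synth_utterance(2, seed = 10)$wave
  cal_t <- render_scene(utt, simulate_brirs(geom, 0, 1.5, fs = FS))
  cal_t10 <- hearsim:::mic_scale(cal_t, 10)
  R <- estimate_noise_covariance(white_mics, CFG)
  w1 <- design_mvdr(estimate_steering_vector(cal_t, "lf", CFG), R)
  w2 <- design_mvdr(estimate_steering_vector(cal_t10, "lf", CFG), R)
  expect_lt(max(Mod(w1 - w2)), 1e-10)
})

test_that("BL keeps residual noise more interaurally diverse than BN", {
  scene <- scene_spec(0, "diffuse", t60 = 0.3, drr_db = 2, seed = 31)
  parts <- build_scene_trial(scene, 0, seed = 31, duration_s = 1.2)
  iacc <- function(cfg) {
    des <- design_beamformer(parts$cal_target, parts$cal_noise, cfg)
    bn <- apply_beamforming(parts$trial$clean_refs$masker, des)
    l <- istft(bn$L)$samples; r <- istft(bn$R)$samples
    abs(stats::cor(l, r))
  }
  expect_lt(iacc("bl"), iacc("bn"))
})
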