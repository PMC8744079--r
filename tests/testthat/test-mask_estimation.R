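test_that("cochleagram has 90 ERB channels and the documented framing", {
  x <- synth_utterance(1, seed = 1)$wave
  C <- cochleagram(x)
  expect_equal(nrow(C$energies), 90L)
  expect_equal(ncol(C$energies), floor((16000 - 410) / 205) + 1)
  expect_error(cochleagram(wave_mono(rnorm(8000), 8000)), "16 kHz")

  # tone at a channel centre peaks in that channel
  for (ch in c(20, 45, 70)) {
    tone <- wave_mono(sin(2 * pi * C$cf[ch] * (0:(FS - 1)) / FS), FS)
    expect_equal(which.max(rowMeans(cochleagram(tone)$energies)), ch)
  }
})

test_that("feature windows concatenate 13 centred frames", {
  x <- synth_utterance(1.2, seed = 2)$wave
  C <- cochleagram(x)
  FW <- feature_windows(C)
  expect_equal(ncol(FW), 13 * 90)
  expect_equal(nrow(FW), ncol(C$energies))

  # constant cochleagram -> identical windows
  Cc <- C; Cc$energies <- matrix(1, 90, 30)
  FWc <- feature_windows(Cc)
  expect_true(all(apply(FWc, 2, function(col) all(col == col[1]))))

  # centre alignment: window t holds frames t-6 .. t+6
  t <- 10
  expect_equal(FW[t, (6 * 90 + 1):(7 * 90)], C$energies[, t])
  expect_equal(FW[t, 1:90], C$energies[, t - 6])
})

test_that("the intelligibility metric is 1 on identity and orders SNRs", {
  utt <- synth_utterance(1.5, seed = 3)$wave
  expect_equal(intelligibility_metric(utt, utt), 1, tolerance = 1e-9)

  lev <- active_speech_level(utt)$active_db
  scores <- sapply(1:10, function(s) {
    set.seed(s)
    nz <- wave_mono(stats::rnorm(length(utt$samples), 0, 0.05), FS)
    intelligibility_metric(utt, nz)
  })
  expect_lt(max(scores), 0.2)

  set.seed(11)
  mix_at <- function(snr) wave_mono(
    utt$samples + stats::rnorm(length(utt$samples), 0, db2lin(lev - snr)), FS)
  expect_lt(intelligibility_metric(utt, mix_at(-5)),
            intelligibility_metric(utt, mix_at(5)))
  expect_error(intelligibility_metric(utt, wave_mono(rnorm(100), FS)),
               "equal length")
})

test_that("metric-optimised masks dominate the reference masks", {
  for (seed in c(2, 5)) {
    utt <- synth_utterance(1, seed = seed)$wave
    short <- wave_mono(utt$samples[1:12000], FS)
    mo <- optimal_mask(short, "metric_opt", seed = seed)
    sc_opt <- attr(mo, "score")

    S <- stft(short, CFG)
    A_clean <- Mod(S$values)
    lev <- active_speech_level(short)
    sigma <- db2lin(lev$active_db + 5)
    set.seed(seed)
    noisy <- lapply(1:4, function(i) {
      nz <- stats::rnorm(length(short$samples), 0, sigma)
      Mod(stft(wave_mono(short$samples + nz, FS), CFG)$values)
    })
    wts <- hearsim:::sii_band_importance(seq(0, 8000, length.out = 129))
    score_of <- function(m) hearsim:::mask_objective(m, A_clean, noisy, wts)
    ibm <- optimal_mask(short, "ibm")
    expect_gte(sc_opt, score_of(ibm) - 1e-9)
    expect_gte(sc_opt, score_of(matrix(1, 129, ncol(ibm))) - 1e-9)
    expect_gte(sc_opt, score_of(matrix(0, 129, ncol(ibm))) - 1e-9)

    # fixed point: no flip of a search-candidate unit improves the score
    w_energy <- sum(hearsim:::sqrt_hann_window(256) ^ 2)
    lsnr <- 10 * log10(pmax(A_clean ^ 2, 1e-30) / (sigma ^ 2 * w_energy))
    cand_all <- which(abs(lsnr) < 8)
    if (length(cand_all) > 150)
      cand_all <- cand_all[order(abs(lsnr[cand_all]))][1:150]
    cand <- cand_all[seq(1, length(cand_all), by = 17)]
    for (u in cand) {
      m2 <- mo; m2[u] <- 1 - m2[u]
      expect_lte(score_of(m2), sc_opt + 1e-9)
    }
  }
  expect_error(optimal_mask(synth_utterance(3, seed = 1)$wave, "metric_opt",
                            cfg = stft_config(fs = 16000)), NA)
  long <- wave_mono(rep(synth_utterance(3, seed = 1)$wave$samples, 2), FS)
  expect_error(optimal_mask(long, "metric_opt"), "5 s")
})

test_that("greedy ascent matches exhaustive search on a restricted toy set", {
  set.seed(17)
  n_bins <- 6; n_fr <- 8
  A_clean <- matrix(stats::rexp(n_bins * n_fr), n_bins, n_fr)
  A_clean[2, ] <- A_clean[2, ] * 4        # a dominant speech band
  noisy <- lapply(1:3, function(i)
    abs(A_clean + matrix(stats::rnorm(n_bins * n_fr, 0, 1), n_bins, n_fr)))
  wts <- rep(1 / n_bins, n_bins)
  init <- (A_clean > stats::median(A_clean)) * 1
  cand <- sample.int(n_bins * n_fr, 12)

  asc <- hearsim:::ascend_mask(init, A_clean, noisy, wts, cand,
                               max_passes = 20)
  # exhaustive over the 2^12 configurations of the candidate units
  best <- -Inf; best_mask <- NULL
  for (code in 0:(2 ^ 12 - 1)) {
    m <- init
    m[cand] <- bitwAnd(bitwShiftR(code, 0:11), 1)
    sc <- hearsim:::mask_objective(m, A_clean, noisy, wts)
    if (sc > best) { best <- sc; best_mask <- m }
  }
  expect_equal(asc$score, best, tolerance = 1e-9)
  expect_equal(asc$mask, best_mask)
})

test_that("every training mixture sits at exactly -5 dB SNR", {
  ts <- make_mask_training_set(6, seed = 21)
  expect_true(all(abs(ts$meta$snr_db - (-5)) < 0.1))
  expect_equal(ncol(ts$features), 1170L)
  expect_equal(ncol(ts$targets), 645L)
  expect_true(all(ts$targets %in% c(0, 1)))
})

test_that("the mask estimator trains, is seeded, and predicts in [0,1]", {
  ts <- make_mask_training_set(12, seed = 30)
  mdl <- train_estimator(ts, epochs = 15, seed = 3)
  lt <- mdl$loss_trace
  expect_lt(lt[length(lt)], 0.5 * lt[1])

  mdl2 <- train_estimator(ts, epochs = 15, seed = 3)
  expect_identical(mdl$layers, mdl2$layers)

  # output layer dimensionality 129 x 5
  expect_equal(nrow(mdl$layers[[length(mdl$layers)]]$W), 645L)

  utt <- synth_utterance(1.2, seed = 91)$wave
  m <- predict_mask(mdl, utt)
  expect_equal(nrow(m$m), 129L)
  expect_true(all(m$m >= 0 & m$m <= 1))

  small <- ts
  small$features <- small$features[1:50, ]; small$targets <- small$targets[1:50, ]
  expect_error(train_estimator(small), "200")
})

test_that("the estimator separates disjoint speech and noise bands", {
  # oracle-separable construction: low-band target vs high-band distractor
  mk_sep <- function(seed) {
    set.seed(seed)
    n <- round(1.2 * FS)
    gate <- rep(stats::rbinom(12, 1, 0.5), each = ceiling(n / 12))[1:n]
    t_axis <- (0:(n - 1)) / FS
    target <- (sin(2 * pi * 500 * t_axis) + sin(2 * pi * 800 * t_axis)) * gate
    distract <- stats::rnorm(n) * (1 - gate)
    distract <- signal::filter(signal::butter(4, 0.7, "high"), distract)
    list(clean = wave_mono(target * 0.05, FS),
         mix = wave_mono((target * 0.05 + 0.05 * as.numeric(distract)), FS))
  }
  feats <- list(); targs <- list()
  for (s in 1:8) {
    d <- mk_sep(s)
    mask <- optimal_mask(d$clean, "ibm")
    C <- cochleagram(d$mix)
    FW <- feature_windows(C)
    map <- hearsim:::coch_to_stft_index(ncol(C$energies), C$hop, C$frame_len,
                                        CFG, ncol(mask))
    patch <- t(vapply(seq_len(ncol(C$energies)), function(t) {
      cols <- pmin(pmax(t + (-2:2), 1), ncol(C$energies))
      as.numeric(mask[, map[cols], drop = FALSE])
    }, numeric(645)))
    feats[[s]] <- FW; targs[[s]] <- patch
  }
  ts <- structure(list(features = do.call(rbind, feats),
                       targets = do.call(rbind, targs)),
                  class = "mask_training_set")
  mdl <- train_estimator(ts, epochs = 20, seed = 2)
  d_test <- mk_sep(99)
  pred <- predict_mask(mdl, d_test$mix)
  truth <- optimal_mask(d_test$clean, "ibm")
  agree <- mean((pred$m > 0.5) == (truth == 1))
  expect_gt(agree, 0.85)
})

test_that("the complex-GMM speech prior is recovered and degenerate-safe", {
  set.seed(7)
  n <- 1e5
  k <- stats::rbinom(n, 1, 0.3)
  v <- ifelse(k == 1, 2.0, 0.2)
  z <- complex(real = stats::rnorm(n, 0, sqrt(v / 2)),
               imaginary = stats::rnorm(n, 0, sqrt(v / 2)))
  pr <- fit_speech_prior(z)
  expect_lt(abs(pr$variances[1] - 0.2) / 0.2, 0.15)
  expect_lt(abs(pr$variances[2] - 2.0) / 2.0, 0.15)
  expect_lt(abs(pr$weights[1] - 0.7), 0.05)
  expect_identical(pr$means, c(0, 0))

  # single-Gaussian data: components collapse towards one another
  z1 <- complex(real = stats::rnorm(n, 0, sqrt(0.5)),
                imaginary = stats::rnorm(n, 0, sqrt(0.5)))
  pr1 <- tryCatch(fit_speech_prior(z1), error = function(e) NULL)
  if (!is.null(pr1)) {
    expect_lt(abs(pr1$variances[2] - pr1$variances[1]) /
                mean(pr1$variances), 1.0)
  }
})

test_that("mask-informed gains respect the mask and the noise-free limit", {
  mx <- make_mixture(0, seed = 40)
  Y <- stft(mx$mix, CFG)
  np <- spp_noise_psd(Y)
  pr <- fit_speech_prior(mx$clean)
  n_fr <- ncol(Y$values)

  # noise-free limit: g -> 1 everywhere
  g1 <- mask_informed_gains(Y, matrix(0.5, 129, n_fr), pr,
                            matrix(1e-30, 129, n_fr))
  expect_true(all(g1$g > 0.999))

  # mask = 0 on noise-only input: strong suppression
  nzY <- stft(wgn_wave(FS, 0.05, seed = 41), CFG)
  nznp <- spp_noise_psd(nzY)
  g0 <- mask_informed_gains(nzY, matrix(0, 129, ncol(nzY$values)), pr, nznp)
  expect_lte(stats::median(g0$g), 2 * db2lin(-30))

  # monotone in the mask value per cell
  prev <- NULL
  for (mv in c(0, 0.25, 0.5, 0.75, 1)) {
    gm <- mask_informed_gains(Y, matrix(mv, 129, n_fr), pr, np)
    if (!is.null(prev)) expect_true(all(gm$g >= prev - 1e-12))
    prev <- gm$g
  }
})
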