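geom <- bte_array_geometry()

test_that("frontal sources give symmetric ear delays, lateral ones a Woodworth ITD", {
  irs0 <- simulate_brirs(geom, 0, 1.5, fs = FS)
  expect_lt(abs(irs0$delays["lf"] - irs0$delays["rf"]), 1)   # samples

  irs60 <- simulate_brirs(geom, 60, 1.5, fs = FS)
  itd_ms <- (irs60$delays[["lf"]] - irs60$delays[["rf"]]) / FS * 1000
  expect_gt(itd_ms, 0.4)
  expect_lt(itd_ms, 0.6)
  # front mic leads the back mic for a frontal source
  expect_lt(irs0$delays[["lf"]], irs0$delays[["lb"]])
})

test_that("reverberant tail decays with the requested T60 (Schroeder)", {
  irs <- simulate_brirs(geom, 0, 2.5, t60 = 0.42, drr_db = 2, fs = FS,
                        seed = 3)
  h <- irs$irs$lf
  tail <- h[-(1:120)]
  edc <- rev(cumsum(rev(tail ^ 2)))
  edc_db <- 10 * log10(edc / edc[1] + 1e-30)
  t <- (seq_along(edc_db) - 1) / FS
  i <- which(edc_db < -5 & edc_db > -25)
  t60_est <- -60 / stats::coef(stats::lm(edc_db[i] ~ t[i]))[[2]]
  expect_lt(abs(t60_est - 0.42) / 0.42, 0.10)
})

test_that("render_scene convolves each channel correctly", {
  src <- wgn_wave(4000, seed = 2)
  unit <- structure(list(irs = list(lf = 1, lb = 1, rf = 1, rb = 1),
                         fs = FS, delays = rep(0, 4), t60 = 0),
                    class = "ir_set")
  out <- render_scene(src, unit)
  expect_equal(out$lf$samples[1:4000], src$samples, tolerance = 1e-12)

  del <- structure(list(irs = list(lf = c(rep(0, 64), 1), lb = 1,
                                   rf = 1, rb = 1),
                        fs = FS, delays = c(64, 0, 0, 0), t60 = 0),
                   class = "ir_set")
  outd <- render_scene(src, del)
  expect_equal(outd$lf$samples[65:4064], src$samples, tolerance = 1e-12)

  # Parseval: output energy ~ input energy * ||ir||^2 for white input
  irs <- simulate_brirs(geom, 30, 1.5, fs = FS)
  long <- wgn_wave(FS * 4, seed = 3)
  o <- render_scene(long, irs)
  ratio <- sum(o$lf$samples ^ 2) /
    (sum(long$samples ^ 2) * sum(irs$irs$lf ^ 2))
  expect_lt(abs(ratio - 1), 0.01)
  expect_error(render_scene(wave_mono(rnorm(100), 8000), irs), "mismatch")
})

third_octave_spectrum <- function(x, fs) {
  sp <- hearsim:::welch_spectrum(x, fs)
  centres <- 10 ^ seq(log10(125), log10(6300), by = 0.1)
  sapply(centres, function(fc) {
    sel <- sp$f >= fc * 2 ^ (-1 / 6) & sp$f < fc * 2 ^ (1 / 6)
    10 * log10(mean(sp$psd[sel]))
  })
}

test_that("speech-shaped noise matches the reference spectrum", {
  # smooth speech-weighted reference (-6 dB/oct above 500 Hz): every
  # third-octave band is well defined, unlike a single harmonic utterance
  set.seed(44)
  ref <- wave_mono(as.numeric(signal::filter(
    signal::butter(1, 500 / 8000), stats::rnorm(10 * FS))), FS)
  nz <- make_noise("ssn", ref, 10, seed = 1)
  b_ref <- third_octave_spectrum(ref$samples, FS)
  b_nz <- third_octave_spectrum(nz$samples, FS)
  expect_lt(max(abs((b_nz - mean(b_nz)) - (b_ref - mean(b_ref)))), 1)

  nz2 <- make_noise("ssn", ref, 10, seed = 2)
  expect_false(isTRUE(all.equal(nz$samples, nz2$samples)))
  b_nz2 <- third_octave_spectrum(nz2$samples, FS)
  expect_lt(max(abs(b_nz2 - b_nz)), 1.5)

  # babble is nonstationary: larger slow-envelope variance than SSN
  env_var <- function(w) {
    blocks <- split(w$samples, ceiling(seq_along(w$samples) / (FS / 8)))
    stats::var(10 * log10(vapply(blocks, function(b) mean(b ^ 2), 1)))
  }
  bb <- make_noise("babble", ref, 4, seed = 1)
  ss <- make_noise("ssn", ref, 4, seed = 1)
  expect_gt(env_var(bb), env_var(ss))
})

test_that("AGC equalisation flattens slow level changes with a common gain", {
  nz <- wgn_wave(6 * FS, 0.1, seed = 3)
  flat <- mic_frame(nz, nz, nz, nz)
  r <- agc_equalize(flat)
  expect_lt(diff(range(r$gain_db[(FS):(5 * FS)])), 0.4)   # ~constant

  # +6 dB level step gets compressed
  stepped <- wave_mono(nz$samples * c(rep(1, 3 * FS), rep(2, 3 * FS)), FS)
  sm <- mic_frame(stepped, stepped, stepped, stepped)
  out <- agc_equalize(sm)
  env_sd <- function(x) {
    blocks <- split(x, ceiling(seq_along(x) / FS))
    stats::sd(10 * log10(vapply(blocks, function(b) mean(b ^ 2), 1)))
  }
  expect_lt(env_sd(out$mics$lf$samples), env_sd(stepped$samples))

  # identical gain on all channels preserves interaural level differences
  l <- wave_mono(stepped$samples, FS)
  rch <- wave_mono(stepped$samples * 0.5, FS)
  m2 <- agc_equalize(mic_frame(l, l, rch, rch))$mics
  seg <- (2 * FS):(2 * FS + 160)
  ild_in <- rms_db(stepped$samples[seg]) - rms_db(stepped$samples[seg] * 0.5)
  ild_out <- rms_db(m2$lf$samples[seg]) - rms_db(m2$rf$samples[seg])
  expect_equal(ild_out, ild_in, tolerance = 1e-9)

  # near-idempotence
  r2 <- agc_equalize(r$mics)
  expect_lt(max(abs(r2$gain_db[(FS):(5 * FS)])), 0.3)
  expect_error(agc_equalize(mic_frame(wave_mono(rnorm(100), FS),
                                      wave_mono(rnorm(100), FS),
                                      wave_mono(rnorm(100), FS),
                                      wave_mono(rnorm(100), FS))), "longer")
})

test_that("the asymmetric SNR level rule holds at 0, -10 and +10 dB", {
  utt <- synth_utterance(1.5, seed = 7)$wave
  t_m <- mic_frame(utt, utt, utt, utt)
  nz <- make_noise("ssn", utt, 4, seed = 2)
  n_m <- mic_frame(nz, nz, nz, nz)
  for (snr in c(0, -10, 10)) {
    r <- set_snr_levels(t_m, n_m, snr)
    t_spl <- active_speech_level(r$target$lf)$active_db + 94
    m_spl <- rms_db(r$masker$lf) + 94
    if (snr >= 0) {
      expect_equal(t_spl, 65, tolerance = 0.1)
      expect_equal(m_spl, 65 - snr, tolerance = 0.1)
    } else {
      expect_equal(m_spl, 65, tolerance = 0.1)
      expect_equal(t_spl, 65 + snr, tolerance = 0.1)
    }
  }
  silent <- mic_frame(wave_mono(rep(0, FS * 2), FS), wave_mono(rep(0, FS * 2), FS),
                      wave_mono(rep(0, FS * 2), FS), wave_mono(rep(0, FS * 2), FS))
  expect_error(set_snr_levels(silent, n_m, 0), "silent")
})

test_that("trial assembly places the masker 900 ms around the target with 100 ms ramps", {
  utt <- synth_utterance(2, seed = 8)$wave
  t_m <- mic_frame(utt, utt, utt, utt)
  nz <- make_noise("ssn", utt, 6, seed = 5)
  n_m <- mic_frame(nz, nz, nz, nz)
  tr <- assemble_trial(t_m, n_m, 0)
  n_target <- length(utt$samples)
  expect_equal(length(tr$mics$lf$samples), n_target + round(1.8 * FS))
  expect_equal(tr$target_onset_s, 0.9)

  # masker envelope rises from 1% to 99% over ~100 ms
  menv <- abs(tr$clean_refs$masker$lf$samples)
  steady <- stats::median(abs(nz$samples)) * sqrt(pi / 2)
  ramp_region <- menv[1:(0.25 * FS)]
  sm <- stats::filter(ramp_region, rep(1 / 160, 160), sides = 2)
  t01 <- which(sm > 0.01 * steady)[1]
  t99 <- which(sm > 0.99 * steady)[1]
  expect_gt((t99 - t01) / FS, 0.05)
  expect_lt((t99 - t01) / FS, 0.15)

  # mixture equals the float sum of the retained clean components
  expect_identical(tr$mics$lf$samples,
                   tr$clean_refs$target$lf$samples +
                     tr$clean_refs$masker$lf$samples)

  short <- mic_frame(wave_mono(nz$samples[1:FS], FS), wave_mono(nz$samples[1:FS], FS),
                     wave_mono(nz$samples[1:FS], FS), wave_mono(nz$samples[1:FS], FS))
  expect_error(assemble_trial(t_m, short, 0), "too short")
})

test_that("synthetic utterances are seeded, harmonic, five-keyword sentences", {
  u1 <- synth_utterance(2, seed = 1)
  u1b <- synth_utterance(2, seed = 1)
  u2 <- synth_utterance(2, seed = 2)
  expect_identical(u1$wave$samples, u1b$wave$samples)
  expect_false(isTRUE(all.equal(u1$wave$samples, u2$wave$samples)))
  expect_equal(u1$keyword_count, 5L)

  # harmonic peaks at multiples of f0 in a voiced segment
  seg <- u1$wave$samples
  e <- abs(seg)
  centre <- which.max(stats::filter(e, rep(1 / 800, 800), sides = 2))
  v <- seg[(centre - 2000):(centre + 2000)]
  sp <- Mod(stats::fft(v * hearsim:::sqrt_hann_window(length(v)) ^ 2)) ^ 2
  f_axis <- (seq_along(sp) - 1) / length(sp) * FS
  f0 <- u1$f0_mean
  harm_power <- sum(sapply(1:8, function(k) {
    sel <- abs(f_axis - k * f0) < 0.25 * f0
    max(sp[sel])
  }))
  mid_power <- sum(sapply(1:8, function(k) {
    sel <- abs(f_axis - (k + 0.5) * f0) < 0.2 * f0
    max(sp[sel])
  }))
  expect_gt(harm_power, 3 * mid_power)
})

test_that("nominal and measured SNR agree for anechoic trials", {
  scene <- scene_spec(0, 60, t60 = 0, seed = 20)
  parts <- build_scene_trial(scene, snr_db = 0, seed = 20, duration_s = 1.5)
  tr <- parts$trial
  on <- round(tr$target_onset_s * FS); off <- round(tr$target_offset_s * FS)
  t_lev <- active_speech_level(
    wave_mono(tr$clean_refs$target$lf$samples[on:off], FS))$active_db
  m_lev <- rms_db(tr$clean_refs$masker$lf$samples[on:off])
  expect_lt(abs((t_lev - m_lev) - 0), 0.5)
})
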