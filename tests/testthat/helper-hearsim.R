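# shared fixtures, all generated in code

FS <- 16000
CFG <- stft_config()

# white Gaussian waveform
wgn_wave <- function(n, sigma = 1, seed = 1, fs = FS) {
  set.seed(seed)
  wave_mono(stats::rnorm(n, 0, sigma), fs)
}

# speech + independent AWGN mixture with known components, at a given SNR
# measured as active speech level over noise RMS
make_mixture <- function(snr_db, seed = 1, duration_s = 1.5) {
  clean <- synth_utterance(duration_s, seed = seed)$wave
  lev <- active_speech_level(clean)$active_db
  set.seed(seed + 1000L)
  noise <- stats::rnorm(length(clean$samples))
  noise <- noise / sqrt(mean(noise ^ 2)) * db2lin(lev - snr_db)
  list(clean = clean,
       noise = wave_mono(noise, clean$fs),
       mix = wave_mono(clean$samples + noise, clean$fs))
}

# oracle output SNR after applying a shared TF gain field to a mixture
# whose clean/noise spectrograms are known
gained_snr_db <- function(g, S_clean, S_noise) {
  10 * log10(sum(Mod(g * S_clean$values) ^ 2) /
               sum(Mod(g * S_noise$values) ^ 2))
}

# mean over ears of the oracle output-SNR improvement of a beamformer
# configuration relative to the unprocessed front microphones
scene_improvement_db <- function(seed, config, t60 = 0.3) {
  scene <- scene_spec(0, "diffuse", t60 = t60, drr_db = 2, seed = seed)
  parts <- build_scene_trial(scene, 0, seed = seed, duration_s = 1.2)
  s0 <- mean(oracle_output_snr(
    parts$trial, design_beamformer(parts$cal_target, parts$cal_noise, "none")))
  des <- design_beamformer(parts$cal_target, parts$cal_noise, config)
  mean(oracle_output_snr(parts$trial, des)) - s0
}
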