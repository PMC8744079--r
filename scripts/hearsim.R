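#!/usr/bin/env Rscript
# Thin command-line front end over the hearsim package.
#
#   Rscript scripts/hearsim.R synthesize --scene anechoic --azimuth 60 \
#       --snr 0 --seed 1 --out scene1
#   Rscript scripts/hearsim.R process --config bn --enhance wiener \
#       --cal-target cal_t.wav --cal-noise cal_n.wav --in mix.wav --out out.wav
#   Rscript scripts/hearsim.R track --true-srt -10 --slope 0.15 --seed 1
#   Rscript scripts/hearsim.R experiment --listeners 10 --seed 1

suppressPackageStartupMessages({
  library(hearsim)
  library(jsonlite)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: hearsim.R <synthesize|process|track|experiment> [options]")
cmd <- argv[1]
opts <- list()
i <- 2
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  opts[[key]] <- argv[i + 1]
  i <- i + 2
}
opt <- function(name, default = NULL) {
  if (!is.null(opts[[name]])) opts[[name]] else default
}

mic_to_matrix <- function(m) {
  cbind(m$lf$samples, m$lb$samples, m$rf$samples, m$rb$samples)
}
matrix_to_mic <- function(d, fs) {
  mic_frame(wave_mono(d[, 1], fs), wave_mono(d[, 2], fs),
            wave_mono(d[, 3], fs), wave_mono(d[, 4], fs))
}

if (cmd == "synthesize") {
  seed <- as.integer(opt("seed", "1"))
  snr <- as.numeric(opt("snr", "0"))
  scene <- if (opt("scene", "anechoic") == "classroom") {
    classroom_scene(opt("location", "middle"), seed = seed)
  } else {
    scene_spec(0, as.numeric(opt("azimuth", "0")), t60 = 0, seed = seed)
  }
  parts <- build_scene_trial(scene, snr_db = snr, seed = seed,
                             duration_s = as.numeric(opt("duration", "2")))
  prefix <- opt("out", "trial")
  wav_write(mic_to_matrix(parts$trial$mics), 16000,
            paste0(prefix, "_mix.wav"))
  wav_write(mic_to_matrix(parts$cal_target), 16000,
            paste0(prefix, "_cal_target.wav"))
  wav_write(mic_to_matrix(parts$cal_noise), 16000,
            paste0(prefix, "_cal_noise.wav"))
  write_json(list(seed = seed, snr_db = snr,
                  target_onset_s = parts$trial$target_onset_s,
                  target_offset_s = parts$trial$target_offset_s,
                  scene = unclass(parts$scene),
                  stft = list(frame_len_ms = 16, overlap_frac = 0.75,
                              fs = 16000)),
             paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  cat("wrote", paste0(prefix, "_{mix,cal_target,cal_noise}.wav"), "\n")

} else if (cmd == "process") {
  fs <- 16000
  rd <- function(p) matrix_to_mic(wav_read(p)$data, fs)
  mix <- rd(opt("in"))
  config <- opt("config", "none")
  regime <- opt("enhance", "none")
  des <- if (config == "none") {
    design_beamformer(mix, mix, "none")
  } else {
    design_beamformer(rd(opt("cal-target")), rd(opt("cal-noise")), config)
  }
  b <- apply_beamforming(mix, des)
  ctx <- list()
  if (regime == "mask") {
    # demo-scale estimator and prior trained on synthetic material
    ts <- make_mask_training_set(as.integer(opt("train-utts", "20")),
                                 seed = as.integer(opt("seed", "1")))
    ctx$model <- train_estimator(ts, epochs = 20,
                                 seed = as.integer(opt("seed", "1")))
    ctx$prior <- fit_speech_prior(synth_utterance(3, seed = 2)$wave)
  }
  e <- enhance(b$L, b$R, b$M, regime, ctx = ctx)
  wav_write(cbind(e$le$samples, e$re$samples), fs, opt("out", "out.wav"))
  cat("wrote", opt("out", "out.wav"), "\n")

} else if (cmd == "track") {
  lm <- listener_model(as.numeric(opt("true-srt", "-10")),
                       as.numeric(opt("slope", "0.15")))
  tr <- run_track(lm, start_snr = as.numeric(opt("start-snr",
                                                 lm$true_srt + 8)),
                  seed = as.integer(opt("seed", "1")))
  cat("SNR sequence:", paste(round(tr$snr_sequence, 1), collapse = " "), "\n")
  cat("responses:   ", paste(tr$responses, collapse = " "), "\n")
  cat(sprintf("SRT estimate: %.2f dB\n", tr$srt))

} else if (cmd == "experiment") {
  n <- as.integer(opt("listeners", "10"))
  seed <- as.integer(opt("seed", "1"))
  conds <- strsplit(opt("conditions", "none,bl,bn"), ",")[[1]]
  scene <- scene_spec(0, "diffuse", t60 = 0.3, drr_db = 2, seed = seed)
  bens <- vapply(conds, function(cn)
    condition_snr_benefit(cn, scene, seed = seed), numeric(1))
  set.seed(seed)
  listeners <- lapply(stats::rnorm(n, -6, 1.5), listener_model)
  res <- run_experiment(listeners, conds, condition_offsets = -bens,
                        seed = seed)
  out <- opt("out", "experiment_results.csv")
  utils::write.csv(res, out, row.names = FALSE)
  print(attr(res, "summary"), row.names = FALSE)
  cat("wrote", out, "\n")

} else {
  stop("unknown subcommand: ", cmd)
}
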