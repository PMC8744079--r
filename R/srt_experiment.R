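# Adaptive speech-reception-threshold staircase, SRT/SRM estimation and the
# batch experiment runner with simulated listeners.

#' Staircase step rule
#'
#' Asymmetric SNR update after one sentence: for 0, 1 or 2 correct keywords
#' the SNR increases by 3, 2 or 1 dB; for 3, 4 or 5 correct it decreases by
#' 1, 2 or 3 dB.
#'
#' @param n_correct Integer count of correct keywords in 0..5.
#' @return SNR change in dB.
#' @export
step_rule <- function(n_correct) {
  if (!n_correct %in% 0:5) stop("n_correct must be in 0..5")
  unname(c(`0` = 3, `1` = 2, `2` = 1, `3` = -1, `4` = -2, `5` = -3)[
    as.character(n_correct)])
}

#' Run one adaptive SRT track
#'
#' Presents 10 scored sentences, updating the SNR with [step_rule()] after
#' each.  If no keyword is correct on the first sentence, that sentence is
#' repeated once at +3 dB; the repeated presentation is the one that is
#' scored and enters the SNR sequence.  The SRT estimate is the mean of the
#' SNRs from the fifth sentence onwards including the SNR that an 11th
#' sentence would have used (7 values).
#'
#' @param listener A [listener_model()], or a function
#'   `function(snr_db) -> n_correct` for deterministic listeners.
#' @param start_snr Starting SNR in dB.
#' @param seed Integer seed for the listener's stochastic responses.
#' @param n_sentences Number of scored sentences (default 10).
#' @return Object of class `track_result`: `snr_sequence`
#'   (`n_sentences + 1` values), `responses`, `srt`, `seed`,
#'   `first_sentence_repeat_used`.
#' @export
run_track <- function(listener, start_snr, seed = 1, n_sentences = 10) {
  respond <- if (is.function(listener)) {
    function(snr) listener(snr)
  } else {
    function(snr) keyword_response(listener, snr)
  }
  set.seed(seed)
  snr <- start_snr
  snr_seq <- numeric(0)
  responses <- integer(0)
  repeat_used <- FALSE
  s <- 1
  while (s <= n_sentences) {
    r <- respond(snr)
    if (s == 1 && r == 0 && !repeat_used) {
      # repeat sentence 1 at +3 dB; the original presentation is discarded
      repeat_used <- TRUE
      snr <- snr + 3
      next
    }
    snr_seq <- c(snr_seq, snr)
    responses <- c(responses, r)
    snr <- snr + step_rule(r)
    s <- s + 1
  }
  snr_seq <- c(snr_seq, snr)                     # hypothetical 11th SNR
  srt <- mean(snr_seq[5:(n_sentences + 1)])
  structure(list(snr_sequence = snr_seq, responses = responses, srt = srt,
                 seed = seed, first_sentence_repeat_used = repeat_used),
            class = "track_result")
}

#' Spatial release from masking
#'
#' @param srt_colocated SRT (dB) with target and masker co-located.
#' @param srt_separated SRT (dB) with the masker spatially separated.
#' @return SRM in dB (positive = benefit of separation).
#' @export
srm <- function(srt_colocated, srt_separated) {
  stopifnot(is.finite(srt_colocated), is.finite(srt_separated))
  srt_colocated - srt_separated
}

#' Run a batch SRT experiment with simulated listeners
#'
#' For every row of the design, runs `n_repeats` adaptive tracks and
#' averages their SRT estimates (two repeats by default, mirroring the
#' two-estimate protocol).  Listener true SRTs may be shifted per condition
#' via `condition_offsets`, the bridge that couples processing benefit
#' (e.g. oracle beamformer SNR improvement) to simulated performance.
#'
#' @param listeners List of [listener_model()]s (one per simulated
#'   listener).
#' @param conditions Character vector of condition labels.
#' @param condition_offsets Named numeric vector: dB added to each
#'   listener's `true_srt` under each condition (default 0 for all).
#' @param start_snr Either a single number or a function
#'   `function(true_srt) -> snr`; default `true_srt + 8` (towards the
#'   higher end of the likely SRT range).
#' @param n_repeats Tracks per cell (default 2).
#' @param seed Integer base seed.
#' @return Data frame with columns `listener`, `condition`, `repeat_idx`,
#'   `srt` plus attribute `"summary"` (per-condition mean/SD of the
#'   per-listener averaged SRTs).
#' @export
run_experiment <- function(listeners, conditions,
                           condition_offsets = NULL,
                           start_snr = NULL, n_repeats = 2, seed = 1) {
  if (is.null(condition_offsets)) {
    condition_offsets <- stats::setNames(rep(0, length(conditions)),
                                         conditions)
  }
  stopifnot(all(conditions %in% names(condition_offsets)))
  rows <- list()
  i <- 0
  for (li in seq_along(listeners)) {
    for (cond in conditions) {
      lm0 <- listeners[[li]]
      lm_c <- listener_model(lm0$true_srt + condition_offsets[[cond]],
                             lm0$slope)
      s0 <- if (is.null(start_snr)) {
        lm_c$true_srt + 8
      } else if (is.function(start_snr)) {
        start_snr(lm_c$true_srt)
      } else start_snr
      for (rep_i in seq_len(n_repeats)) {
        i <- i + 1
        tr <- run_track(lm_c, s0,
                        seed = (seed * 100003L + li * 1009L +
                                  match(cond, conditions) * 101L + rep_i) %%
                          .Machine$integer.max)
        rows[[i]] <- data.frame(listener = li, condition = cond,
                                repeat_idx = rep_i, srt = tr$srt)
      }
    }
  }
  res <- do.call(rbind, rows)
  cell <- stats::aggregate(srt ~ listener + condition, res, mean)
  summ <- do.call(rbind, lapply(split(cell, cell$condition), function(d)
    data.frame(condition = d$condition[1], mean_srt = mean(d$srt),
               sd_srt = stats::sd(d$srt), n = nrow(d))))
  attr(res, "summary") <- summ
  res
}

#' Oracle SNR benefit of a processing condition
#'
#' Builds a synthetic trial from a scene specification, designs the
#' requested beamformer from matched calibration material, and measures the
#' better-ear oracle output SNR improvement relative to the unprocessed
#' front microphones.  Used to couple processing conditions to simulated
#' listeners' true SRTs.
#'
#' @param config Beamformer configuration (`"none"`, `"bl"`, `"bn"`).
#' @param scene A [scene_spec()].
#' @param seed Integer seed.
#' @param duration_s Trial target duration.
#' @return SNR improvement in dB (better ear), >= 0 up to measurement noise
#'   for MVDR designs.
#' @export
condition_snr_benefit <- function(config, scene, seed = 1,
                                  duration_s = 1.5) {
  parts <- build_scene_trial(scene, snr_db = 0, seed = seed,
                             duration_s = duration_s)
  none <- design_beamformer(parts$cal_target, parts$cal_noise, "none")
  snr0 <- max(oracle_output_snr(parts$trial, none))
  if (config == "none") return(0)
  des <- design_beamformer(parts$cal_target, parts$cal_noise, config)
  max(oracle_output_snr(parts$trial, des)) - snr0
}

#' Build a complete synthetic trial plus calibration material
#'
#' Renders a target utterance and a masker (point-source SSN or diffuse
#' field per the scene), applies the AGC equalisation for reverberant
#' scenes, sets presentation levels by the asymmetric SNR rule and
#' assembles the trial.  Also returns target-alone and noise-alone
#' calibration recordings rendered through the same scene for beamformer
#' design.
#'
#' @param scene A [scene_spec()].
#' @param snr_db Nominal trial SNR.
#' @param seed Integer seed.
#' @param duration_s Target utterance duration.
#' @param cal_target_s,cal_noise_s Calibration durations (defaults 5 and
#'   10 s).
#' @return List: `trial` (a `trial_stimulus`), `cal_target`, `cal_noise`
#'   ([mic_frame()]s), `geom`, `scene`.
#' @export
build_scene_trial <- function(scene, snr_db = 0, seed = 1,
                              duration_s = 2, cal_target_s = 5,
                              cal_noise_s = 10) {
  stopifnot(inherits(scene, "scene_spec"))
  geom <- bte_array_geometry()
  fs <- 16000
  utt <- synth_utterance(min(3, max(1, duration_s)), seed = seed)$wave
  irs_t <- simulate_brirs(geom, scene$target_azimuth, scene$source_distance,
                          t60 = scene$t60, drr_db = scene$drr_db, fs = fs,
                          seed = scene$seed)
  target <- render_scene(utt, irs_t)
  ref_long <- synth_utterance(3, seed = seed + 5000L)$wave
  diffuse <- identical(scene$noise_azimuth, "diffuse")
  masker_dur <- duration_s + 2.5
  masker <- if (diffuse) {
    render_diffuse_noise(ref_long, masker_dur, geom, scene)
  } else {
    nz <- make_noise("ssn", ref_long, masker_dur, seed = seed + 9000L)
    irs_n <- simulate_brirs(geom, scene$noise_azimuth,
                            scene$source_distance, t60 = scene$t60,
                            drr_db = scene$drr_db, fs = fs,
                            seed = scene$seed + 1L)
    render_scene(nz, irs_n)
  }
  if (scene$t60 > 0 && length(masker$lf$samples) > fs) {
    masker <- agc_equalize(masker)$mics
  }
  # reference = front mic of the ear nearer the noise-free direction
  ref_mic <- if (!diffuse && is.numeric(scene$noise_azimuth) &&
                 scene$noise_azimuth < 0) "rf" else "lf"
  lev <- set_snr_levels(target, masker, snr_db, ref = ref_mic)
  trial <- assemble_trial(lev$target, lev$masker, snr_db)
  # calibration recordings through the same scene
  cal_utt <- synth_utterance(3, seed = seed + 7000L)$wave
  cal_t <- render_scene(cal_utt, irs_t)
  n_rep <- ceiling(cal_target_s / 3)
  cal_t <- mic_apply(cal_t, function(w)
    wave_mono(rep(w$samples, n_rep)[seq_len(round(cal_target_s * fs))], fs))
  cal_n <- if (diffuse) {
    sc2 <- scene
    sc2$seed <- scene$seed + 77L
    render_diffuse_noise(ref_long, cal_noise_s, geom, sc2)
  } else {
    nz2 <- make_noise("ssn", ref_long, cal_noise_s, seed = seed + 11000L)
    irs_n2 <- simulate_brirs(geom, scene$noise_azimuth,
                             scene$source_distance, t60 = scene$t60,
                             drr_db = scene$drr_db, fs = fs,
                             seed = scene$seed + 1L)
    render_scene(nz2, irs_n2)
  }
  list(trial = trial, cal_target = cal_t, cal_noise = cal_n,
       geom = geom, scene = scene)
}
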