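# MVDR beamformer design from calibration recordings and STFT-domain
# application.  Three configurations: "none" (front-microphone pass-through),
# "bl" (bilateral: independent 2-mic MVDR per ear), "bn" (binaural: one 4-mic
# MVDR per ear).  Reference microphones: LF for the L output, RF for the R
# output; the mask-path M output is always a 4-mic MVDR referenced to LF, so
# M coincides with L in the "bn" configuration.

#' Per-bin noise spatial covariance from a noise-alone calibration recording
#'
#' Sample covariance of the STFT microphone vectors across frames,
#' Hermitian-symmetrised, with diagonal loading
#' `delta = loading * trace(R)/channels` per bin.
#'
#' @param noise_cal [mic_frame()] of noise-alone calibration (>= 2 s
#'   recommended; at least `8 * channels` frames required).
#' @param cfg [stft_config()].
#' @param channels Character vector of microphone names to use (default all
#'   four).
#' @param loading Relative diagonal loading (default 1e-3).
#' @return Object of class `noise_covariance`: complex array
#'   `R[ch, ch, bin]`, `channels`, `cfg`.
#' @export
estimate_noise_covariance <- function(noise_cal, cfg = stft_config(),
                                      channels = mic_names(),
                                      loading = 1e-3) {
  stopifnot(inherits(noise_cal, "mic_frame"))
  specs <- lapply(channels, function(ch) stft(noise_cal[[ch]], cfg)$values)
  n_ch <- length(channels)
  n_frames <- ncol(specs[[1]])
  if (n_frames < 8 * n_ch)
    stop("noise calibration too short: ", n_frames, " frames for ",
         n_ch, " channels")
  n_bins <- nrow(specs[[1]])
  R <- array(0i, dim = c(n_ch, n_ch, n_bins))
  for (k in seq_len(n_bins)) {
    X <- t(vapply(specs, function(s) s[k, ], complex(n_frames)))  # ch x frames
    Rk <- (X %*% Conj(t(X))) / n_frames
    Rk <- (Rk + Conj(t(Rk))) / 2
    Rk <- Rk + diag(n_ch) * (loading * Re(sum(diag(Rk))) / n_ch + 1e-30)
    R[, , k] <- Rk
  }
  structure(list(R = R, channels = channels, cfg = cfg),
            class = "noise_covariance")
}

#' Relative-transfer-function steering vector from a target-alone calibration
#'
#' Per frequency bin, the principal eigenvector of the target calibration
#' covariance, rescaled so the reference-microphone component equals
#' exactly 1 + 0i.  Bins whose target energy falls below `energy_floor`
#' relative to the strongest bin default to a pass-through unit vector at the
#' reference microphone.
#'
#' @param target_cal [mic_frame()] of target-alone calibration.
#' @param ref Reference microphone name (must be in `channels`).
#' @param cfg [stft_config()].
#' @param channels Microphones to use.
#' @param energy_floor Relative energy floor for silent-bin fallback.
#' @return Object of class `steering_vector`: complex matrix
#'   `d[ch, bin]`, `ref`, `channels`.
#' @export
estimate_steering_vector <- function(target_cal, ref = "lf",
                                     cfg = stft_config(),
                                     channels = mic_names(),
                                     energy_floor = 1e-6) {
  stopifnot(ref %in% channels)
  specs <- lapply(channels, function(ch) stft(target_cal[[ch]], cfg)$values)
  n_ch <- length(channels)
  n_bins <- nrow(specs[[1]])
  n_frames <- ncol(specs[[1]])
  ref_i <- match(ref, channels)
  d <- matrix(0i, n_ch, n_bins)
  bin_energy <- numeric(n_bins)
  covs <- vector("list", n_bins)
  for (k in seq_len(n_bins)) {
    X <- t(vapply(specs, function(s) s[k, ], complex(n_frames)))
    Rk <- (X %*% Conj(t(X))) / n_frames
    covs[[k]] <- (Rk + Conj(t(Rk))) / 2
    bin_energy[k] <- Re(sum(diag(Rk)))
  }
  floor_e <- max(bin_energy) * energy_floor
  unit <- rep(0i, n_ch); unit[ref_i] <- 1 + 0i
  for (k in seq_len(n_bins)) {
    if (bin_energy[k] <= floor_e) {
      d[, k] <- unit
      next
    }
    ev <- eigen(covs[[k]], symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (Mod(v[ref_i]) < 1e-12) {
      d[, k] <- unit
    } else {
      d[, k] <- v / v[ref_i]
    }
  }
  structure(list(d = d, ref = ref, channels = channels, cfg = cfg),
            class = "steering_vector")
}

#' MVDR weights for one steering vector / noise covariance pair
#'
#' `w = R^-1 d / (d^H R^-1 d)` per bin, which minimises output noise power
#' `w^H R w` subject to the distortionless constraint `w^H d = 1` (the
#' target component at the reference microphone passes unaltered).  Bins
#' whose loaded covariance is ill-conditioned (condition number > 1e8)
#' receive extra diagonal loading with a warning.
#'
#' @param d A `steering_vector`.
#' @param R A `noise_covariance` over the same channels.
#' @return Complex weight matrix `w[ch, bin]` with attribute `"ref"`.
#' @export
design_mvdr <- function(d, R) {
  stopifnot(inherits(d, "steering_vector"), inherits(R, "noise_covariance"),
            identical(d$channels, R$channels))
  n_ch <- nrow(d$d)
  n_bins <- ncol(d$d)
  w <- matrix(0i, n_ch, n_bins)
  warned <- FALSE
  for (k in seq_len(n_bins)) {
    Rk <- R$R[, , k]
    ev <- eigen(Rk, symmetric = TRUE, only.values = TRUE)$values
    if (max(ev) / max(min(ev), 1e-300) > 1e8) {
      if (!warned) {
        warning("ill-conditioned noise covariance; adding extra loading")
        warned <- TRUE
      }
      Rk <- Rk + diag(n_ch) * max(ev) * 1e-8
    }
    dk <- d$d[, k]
    Rinv_d <- solve(Rk, dk)
    wk <- Rinv_d / sum(Conj(dk) * Rinv_d)
    # force the distortionless constraint to machine precision
    wk <- wk / Conj(sum(Conj(wk) * dk))
    w[, k] <- wk
  }
  attr(w, "ref") <- d$ref
  w
}

#' Design a full beamformer from calibration recordings
#'
#' @param cal_target [mic_frame()] target-alone calibration recording.
#' @param cal_noise [mic_frame()] noise-alone calibration recording.
#' @param config `"none"`, `"bl"` (bilateral 2-mic per ear) or `"bn"`
#'   (binaural 4-mic).
#' @param cfg [stft_config()].
#' @return Object of class `beamformer_design` with per-output weights and
#'   channel lists.  The mask-path output M is a binaural 4-mic MVDR with
#'   reference LF in every configuration (so `M == L` for `"bn"`).
#' @export
design_beamformer <- function(cal_target, cal_noise,
                              config = c("none", "bl", "bn"),
                              cfg = stft_config()) {
  config <- match.arg(config)
  outputs <- list()
  if (config != "none") {
    R4 <- estimate_noise_covariance(cal_noise, cfg, mic_names())
    d4_l <- estimate_steering_vector(cal_target, "lf", cfg, mic_names())
    w_m <- design_mvdr(d4_l, R4)
    if (config == "bn") {
      d4_r <- estimate_steering_vector(cal_target, "rf", cfg, mic_names())
      outputs$L <- list(w = w_m, channels = mic_names())
      outputs$R <- list(w = design_mvdr(d4_r, R4), channels = mic_names())
    } else {
      Rl <- estimate_noise_covariance(cal_noise, cfg, c("lf", "lb"))
      Rr <- estimate_noise_covariance(cal_noise, cfg, c("rf", "rb"))
      dl <- estimate_steering_vector(cal_target, "lf", cfg, c("lf", "lb"))
      dr <- estimate_steering_vector(cal_target, "rf", cfg, c("rf", "rb"))
      outputs$L <- list(w = design_mvdr(dl, Rl), channels = c("lf", "lb"))
      outputs$R <- list(w = design_mvdr(dr, Rr), channels = c("rf", "rb"))
    }
    outputs$M <- list(w = w_m, channels = mic_names())
  }
  structure(list(config = config, outputs = outputs, cfg = cfg,
                 refs = c(L = "lf", R = "rf", M = "lf")),
            class = "beamformer_design")
}

#' Apply a beamformer design to a microphone frame
#'
#' Computes per-bin inner products of the design weights with the STFT
#' microphone vectors.  Configuration `"none"` returns the front-microphone
#' spectrograms unchanged (M falls back to LF).
#'
#' @param mics [mic_frame()].
#' @param design [design_beamformer()] output.
#' @return List of `spectrogram`s `L`, `R`, `M`.
#' @export
apply_beamforming <- function(mics, design) {
  stopifnot(inherits(mics, "mic_frame"), inherits(design, "beamformer_design"))
  cfg <- design$cfg
  if (mics$lf$fs != cfg$fs) stop("sample-rate mismatch with design")
  specs <- lapply(mic_names(), function(ch) stft(mics[[ch]], cfg))
  names(specs) <- mic_names()
  if (design$config == "none") {
    return(list(L = specs$lf, R = specs$rf, M = specs$lf))
  }
  combine <- function(out) {
    w <- out$w
    chans <- out$channels
    acc <- 0
    for (i in seq_along(chans)) {
      acc <- acc + Conj(w[i, ]) * specs[[chans[i]]]$values
    }
    S <- specs[[chans[1]]]
    S$values <- acc
    S
  }
  list(L = combine(design$outputs$L),
       R = combine(design$outputs$R),
       M = combine(design$outputs$M))
}

#' Oracle output-SNR of a beamformer on a decomposable scene
#'
#' Passes the clean target and masker components of a trial separately
#' through the (linear) beamformer and reports the target-to-masker power
#' ratio of each output, in dB.  Only possible for synthetic stimuli whose
#' clean components are known.
#'
#' @param trial A `trial_stimulus` from [assemble_trial()].
#' @param design A `beamformer_design`.
#' @return Named numeric: output SNR (dB) for `L` and `R`.
#' @export
oracle_output_snr <- function(trial, design) {
  bt <- apply_beamforming(trial$clean_refs$target, design)
  bm <- apply_beamforming(trial$clean_refs$masker, design)
  snr_of <- function(S_t, S_m) {
    10 * log10(sum(Mod(S_t$values) ^ 2) / sum(Mod(S_m$values) ^ 2))
  }
  c(L = snr_of(bt$L, bm$L), R = snr_of(bt$R, bm$R))
}
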