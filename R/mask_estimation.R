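# Mask-informed enhancement: cochleagram features, intelligibility-optimal
# binary training masks, a small trainable mask estimator, the two-component
# zero-mean complex-Gaussian speech prior and the log-spectral-amplitude
# MMSE gain rule.

# ERB auditory scale
hz_to_erb <- function(f) 21.4 * log10(0.00437 * f + 1)
erb_to_hz <- function(e) (10 ^ (e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' Cochleagram features
#'
#' 90-channel ERB-spaced (50 Hz to 8 kHz) filterbank log-energies computed
#' per frame (25.6 ms frames, 50% overlap).  Channel energies are obtained
#' by integrating the frame power spectrum under fourth-order
#' gammatone-shaped frequency weightings.
#'
#' @param x A [wave_mono()] at 16 kHz.
#' @param n_channels Number of channels (default 90).
#' @param frame_ms Frame duration (default 25.6 ms).
#' @return Object of class `cochleagram`: `energies` (channels x frames,
#'   log energy), `cf` (channel centre frequencies, Hz), `frame_len`,
#'   `hop` (samples), `fs`.
#' @export
cochleagram <- function(x, n_channels = 90, frame_ms = 25.6) {
  stopifnot(inherits(x, "wave_mono"))
  if (x$fs != 16000) stop("cochleagram expects fs = 16 kHz")
  fs <- x$fs
  frame <- as.integer(round(frame_ms / 1000 * fs))   # 410 samples
  hop <- as.integer(round(frame / 2))                # 205
  n <- length(x$samples)
  if (n < frame) stop("signal shorter than one cochleagram frame")
  n_frames <- as.integer(floor((n - frame) / hop) + 1)
  nfft <- stats::nextn(frame, 2)                     # 512
  w <- 0.5 * (1 - cos(2 * pi * (0:(frame - 1)) / frame))
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  cf <- erb_to_hz(seq(hz_to_erb(50), hz_to_erb(8000),
                      length.out = n_channels))
  # gammatone power response per channel on the FFT grid
  W <- vapply(cf, function(fc) {
    b <- 1.019 * erb_bandwidth(fc)
    (1 + ((f - fc) / b) ^ 2) ^ (-4)
  }, numeric(length(f)))                             # freq x channels
  E <- matrix(0, n_channels, n_frames)
  for (m in seq_len(n_frames)) {
    seg <- x$samples[((m - 1) * hop + 1):((m - 1) * hop + frame)] * w
    X <- stats::fft(c(seg, rep(0, nfft - frame)))[1:(nfft / 2 + 1)]
    E[, m] <- crossprod(W, Mod(X) ^ 2)
  }
  structure(list(energies = log(E + 1e-12), cf = cf, frame_len = frame,
                 hop = hop, fs = fs),
            class = "cochleagram")
}

#' Sliding 13-frame feature windows
#'
#' Concatenates 13 consecutive cochleagram frames (centre frame +/- 6,
#' edges padded by repetition) into one 1170-dimensional feature vector per
#' frame position.
#'
#' @param C A [cochleagram()].
#' @param width Window width in frames (default 13).
#' @return Numeric matrix, one row per frame position, `width * channels`
#'   columns; attribute `"centre"` holds the centre-frame indices.
#' @export
feature_windows <- function(C, width = 13) {
  stopifnot(inherits(C, "cochleagram"), width %% 2 == 1)
  E <- C$energies
  n_ch <- nrow(E); n_fr <- ncol(E)
  half <- (width - 1) / 2
  idx_pad <- c(rep(1, half), seq_len(n_fr), rep(n_fr, half))
  out <- matrix(0, n_fr, width * n_ch)
  for (t in seq_len(n_fr)) {
    cols <- idx_pad[t:(t + width - 1)]
    out[t, ] <- as.numeric(E[, cols])
  }
  attr(out, "centre") <- seq_len(n_fr)
  out
}

# SII-style one-third-octave band importance (ANSI S3.5 speech-in-quiet
# shape), interpolated onto arbitrary frequencies and renormalised.
sii_band_importance <- function(freqs) {
  f0 <- c(160, 200, 250, 315, 400, 500, 630, 800, 1000, 1250, 1600,
          2000, 2500, 3150, 4000, 5000, 6300, 8000)
  imp <- c(0.0083, 0.0095, 0.0150, 0.0289, 0.0440, 0.0578, 0.0653,
           0.0711, 0.0818, 0.0844, 0.0882, 0.0898, 0.0868, 0.0844,
           0.0771, 0.0527, 0.0364, 0.0185)
  w <- stats::approx(f0, imp, xout = pmax(min(f0), pmin(max(f0), freqs)),
                     rule = 2)$y
  w[freqs < 100] <- 0
  w / sum(w)
}

# Envelope-correlation intelligibility score on amplitude matrices.
# Correlations of clean vs processed envelope segments per band, clipped to
# [0,1], band-importance weighted and averaged over segments.
envelope_correlation_score <- function(A_clean, A_proc, weights,
                                       seg_len = 96, seg_hop = 48) {
  stopifnot(all(dim(A_clean) == dim(A_proc)))
  n_bins <- nrow(A_clean); n_fr <- ncol(A_clean)
  if (n_fr < seg_len) { seg_len <- n_fr; seg_hop <- n_fr }
  starts <- seq(1, n_fr - seg_len + 1, by = seg_hop)
  total <- 0; wsum <- 0
  for (s in starts) {
    cols <- s:(s + seg_len - 1)
    Xc <- A_clean[, cols, drop = FALSE]
    Xp <- A_proc[, cols, drop = FALSE]
    mc <- rowMeans(Xc); mp <- rowMeans(Xp)
    xc <- Xc - mc; xp <- Xp - mp
    num <- rowSums(xc * xp)
    den <- sqrt(rowSums(xc ^ 2) * rowSums(xp ^ 2))
    r <- ifelse(den > 1e-12 * seg_len, num / den, 0)
    r <- pmax(0, pmin(1, r))
    # only bands carrying clean speech energy (within 40 dB of the
    # strongest band of the segment) are informative
    e_band <- rowSums(Xc ^ 2)
    act <- e_band > max(e_band) * 1e-4 & rowSums(xc ^ 2) > 1e-12
    total <- total + sum(weights * r * act)
    wsum <- wsum + sum(weights * act)
  }
  if (wsum <= 0) return(0)
  total / wsum
}

#' Band-importance-weighted envelope-correlation intelligibility metric
#'
#' A STOI-style metric on the shared 129-bin STFT grid: short-time amplitude
#' envelopes of clean and processed signals are compared by clipped
#' correlation over 384-ms segments per frequency bin, and the per-bin
#' scores are combined with SII-derived band-importance weights.
#'
#' @param clean,processed Aligned [wave_mono()]s of equal length.
#' @param cfg [stft_config()].
#' @return Scalar score in [0, 1]; 1 for identical signals.
#' @export
intelligibility_metric <- function(clean, processed, cfg = stft_config()) {
  stopifnot(inherits(clean, "wave_mono"), inherits(processed, "wave_mono"))
  if (length(clean$samples) != length(processed$samples))
    stop("clean and processed must have equal length")
  Ac <- Mod(stft(clean, cfg)$values)
  Ap <- Mod(stft(processed, cfg)$values)
  freqs <- seq(0, cfg$fs / 2, length.out = cfg$n_bins)
  envelope_correlation_score(Ac, Ap, sii_band_importance(freqs))
}

# objective for mask search: mean metric over noise realisations of the
# masked noisy amplitude vs the clean amplitude
mask_objective <- function(mask, A_clean, noisy_amps, weights) {
  mean(vapply(noisy_amps, function(An)
    envelope_correlation_score(A_clean, mask * An, weights), numeric(1)))
}

# greedy single-flip coordinate ascent over the candidate units
ascend_mask <- function(mask, A_clean, noisy_amps, weights, candidates,
                        max_passes = 3) {
  best <- mask_objective(mask, A_clean, noisy_amps, weights)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (u in candidates) {
      mask[u] <- 1 - mask[u]
      sc <- mask_objective(mask, A_clean, noisy_amps, weights)
      if (sc > best + 1e-12) {
        best <- sc
        improved <- TRUE
      } else {
        mask[u] <- 1 - mask[u]
      }
    }
    if (!improved) break
  }
  list(mask = mask, score = best)
}

#' Intelligibility-optimal (or ideal) binary training mask
#'
#' Mode `"ibm"` thresholds the local SNR of the clean spectrogram against
#' the expected AWGN power per bin (0 dB local criterion).  Mode
#' `"metric_opt"` runs greedy single-flip coordinate ascent on the expected
#' intelligibility score over `n_noise` AWGN realisations at `snr_db`,
#' starting from the best of the IBM, all-ones and all-zeros masks and
#' restricted to the most uncertain TF units (local SNR within
#' `uncertain_db` of the criterion, capped at `max_candidates`), until no
#' single flip improves the objective.
#'
#' @param clean A [wave_mono()] (<= 5 s for `"metric_opt"`).
#' @param mode `"ibm"` or `"metric_opt"`.
#' @param snr_db Corruption SNR for the optimisation noise (default -5).
#' @param n_noise Number of AWGN realisations averaged (default 4).
#' @param seed Integer seed for the noise realisations.
#' @param cfg [stft_config()].
#' @param uncertain_db Local-SNR band defining candidate units.
#' @param max_candidates Cap on the number of candidate units.
#' @return Binary matrix (`n_bins` x frames) with attribute `"score"`
#'   (`metric_opt` objective; `NA` for `"ibm"`).
#' @export
optimal_mask <- function(clean, mode = c("ibm", "metric_opt"), snr_db = -5,
                         n_noise = 4, seed = 1, cfg = stft_config(),
                         uncertain_db = 8, max_candidates = 150) {
  mode <- match.arg(mode)
  stopifnot(inherits(clean, "wave_mono"))
  dur <- length(clean$samples) / clean$fs
  if (mode == "metric_opt" && dur > 5)
    stop("metric_opt is combinatorially expensive; chunk inputs to <= 5 s")
  S_clean <- stft(clean, cfg)
  A_clean <- Mod(S_clean$values)
  lev <- active_speech_level(clean)
  sigma <- db2lin(lev$active_db - snr_db)          # AWGN RMS for snr_db
  w_energy <- sum(sqrt_hann_window(cfg$frame_len) ^ 2)
  noise_bin_power <- sigma ^ 2 * w_energy          # E|N(k)|^2, flat over k
  local_snr_db <- 10 * log10(pmax(A_clean ^ 2, 1e-30) / noise_bin_power)
  ibm <- (local_snr_db > 0) * 1
  if (mode == "ibm") {
    attr(ibm, "score") <- NA_real_
    return(ibm)
  }
  set.seed(seed)
  noisy_amps <- lapply(seq_len(n_noise), function(i) {
    nz <- wave_mono(stats::rnorm(length(clean$samples), 0, sigma), clean$fs)
    Mod(stft(wave_mono(clean$samples + nz$samples, clean$fs), cfg)$values)
  })
  freqs <- seq(0, cfg$fs / 2, length.out = cfg$n_bins)
  weights <- sii_band_importance(freqs)
  cand <- which(abs(local_snr_db) < uncertain_db)
  if (length(cand) > max_candidates) {
    cand <- cand[order(abs(local_snr_db[cand]))][seq_len(max_candidates)]
  }
  inits <- list(ibm = ibm,
                ones = matrix(1, nrow(ibm), ncol(ibm)),
                zeros = matrix(0, nrow(ibm), ncol(ibm)))
  scores <- vapply(inits, mask_objective, numeric(1), A_clean = A_clean,
                   noisy_amps = noisy_amps, weights = weights)
  res <- ascend_mask(inits[[which.max(scores)]], A_clean, noisy_amps,
                     weights, cand)
  out <- res$mask
  attr(out, "score") <- res$score
  out
}

# ---- mask estimator (small feed-forward network, pure matrix code) -------

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  layers <- vector("list", length(sizes) - 1)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(sizes[i + 1] * fan_in, 0, sqrt(2 / fan_in)),
                 sizes[i + 1], fan_in),
      b = rep(0, sizes[i + 1]))
  }
  layers
}

mlp_forward <- function(layers, X) {            # X: features x batch
  acts <- list(X)
  n_l <- length(layers)
  for (i in seq_len(n_l)) {
    Z <- layers[[i]]$W %*% acts[[i]] + layers[[i]]$b
    acts[[i + 1]] <- if (i < n_l) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  acts
}

#' Train the TF-mask estimator
#'
#' A small feed-forward network (1170 inputs, two ReLU hidden layers,
#' 645 = 129 x 5 sigmoid outputs) trained with Adam on binary cross-entropy
#' against the binary mask patches.  Deterministic under a fixed seed.
#'
#' @param train Training set from [make_mask_training_set()] (list with
#'   `features` rows x 1170 and `targets` rows x 645 in \{0,1\}).
#' @param hidden Hidden-layer widths (default `c(96, 96)`).
#' @param epochs Training epochs (default 30).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed (weight init and shuffling).
#' @return Object of class `mask_estimator`: layers, feature scaling, and
#'   the per-epoch `loss_trace`.
#' @export
train_estimator <- function(train, hidden = c(96, 96), epochs = 30,
                            lr = 1e-3, batch_size = 64, seed = 1) {
  X <- train$features
  Yt <- train$targets
  stopifnot(is.matrix(X), is.matrix(Yt), nrow(X) == nrow(Yt))
  if (nrow(X) < 200) stop("need >= 200 training patches, got ", nrow(X))
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-6)
  Xs <- t((t(X) - mu) / sdv)                     # rows = samples
  sizes <- c(ncol(X), hidden, ncol(Yt))
  layers <- mlp_init(sizes, seed)
  mstate <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- mstate
  n <- nrow(Xs)
  loss_trace <- numeric(epochs)
  step <- 0
  beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(n, b0 + batch_size - 1)]
      Xb <- t(Xs[idx, , drop = FALSE])           # features x batch
      Yb <- t(Yt[idx, , drop = FALSE])
      acts <- mlp_forward(layers, Xb)
      P <- acts[[length(acts)]]
      eps <- 1e-7
      loss <- -mean(Yb * log(P + eps) + (1 - Yb) * log(1 - P + eps))
      ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
      delta <- (P - Yb) / length(idx)            # dL/dZ for sigmoid+BCE
      step <- step + 1
      for (i in rev(seq_along(layers))) {
        gW <- delta %*% t(acts[[i]])
        gb <- rowSums(delta)
        if (i > 1) {
          delta <- (t(layers[[i]]$W) %*% delta) * (acts[[i]] > 0)
        }
        mstate[[i]]$W <- beta1 * mstate[[i]]$W + (1 - beta1) * gW
        mstate[[i]]$b <- beta1 * mstate[[i]]$b + (1 - beta1) * gb
        vstate[[i]]$W <- beta2 * vstate[[i]]$W + (1 - beta2) * gW ^ 2
        vstate[[i]]$b <- beta2 * vstate[[i]]$b + (1 - beta2) * gb ^ 2
        corr1 <- 1 - beta1 ^ step; corr2 <- 1 - beta2 ^ step
        layers[[i]]$W <- layers[[i]]$W -
          lr * (mstate[[i]]$W / corr1) / (sqrt(vstate[[i]]$W / corr2) + epsadam)
        layers[[i]]$b <- layers[[i]]$b -
          lr * (mstate[[i]]$b / corr1) / (sqrt(vstate[[i]]$b / corr2) + epsadam)
      }
    }
    loss_trace[ep] <- ep_loss / ep_n
    if (!is.finite(loss_trace[ep])) stop("training diverged (loss not finite)")
  }
  structure(list(layers = layers, mu = mu, sd = sdv,
                 n_bins = 129L, patch_frames = 5L,
                 loss_trace = loss_trace),
            class = "mask_estimator")
}

# map cochleagram frame centres onto STFT frame indices (nearest centre)
coch_to_stft_index <- function(n_coch, coch_hop, coch_frame,
                               cfg, n_stft) {
  centre <- (seq_len(n_coch) - 1) * coch_hop + coch_frame / 2
  pad <- cfg$frame_len - cfg$hop
  stft_centre <- (seq_len(n_stft) - 1) * cfg$hop + cfg$frame_len / 2 - pad
  vapply(centre, function(s) which.min(abs(stft_centre - s)), integer(1))
}

#' Build a mask-estimator training set
#'
#' Synthesises utterances, corrupts each with additive white Gaussian noise
#' at exactly -5 dB SNR (measured as active speech level over noise RMS),
#' computes the binary target mask from the clean signal, and pairs each
#' 13-frame cochleagram feature window of the noisy signal with its
#' 129 x 5 binary mask patch.
#'
#' @param n_utts Number of utterances.
#' @param seed Integer seed.
#' @param mode Target-mask mode passed to [optimal_mask()]; default
#'   `"ibm"` (the metric-optimised target is available but far slower).
#' @param snr_db Corruption SNR (default -5).
#' @param duration_s Utterance duration (default 1.2 s).
#' @param windows_per_utt Feature windows sampled per utterance (default
#'   40; `Inf` keeps all).
#' @param cfg [stft_config()].
#' @return List of class `mask_training_set`: `features`, `targets`,
#'   `meta` (data frame with per-utterance seed and measured SNR).
#' @export
make_mask_training_set <- function(n_utts, seed = 1, mode = "ibm",
                                   snr_db = -5, duration_s = 1.2,
                                   windows_per_utt = 40,
                                   cfg = stft_config()) {
  feats <- list(); targs <- list()
  meta <- data.frame(utt = seq_len(n_utts), seed = seed + seq_len(n_utts),
                     snr_db = NA_real_)
  for (u in seq_len(n_utts)) {
    utt_seed <- seed + u
    clean <- synth_utterance(duration_s, seed = utt_seed)$wave
    lev <- active_speech_level(clean)
    sigma <- db2lin(lev$active_db - snr_db)
    set.seed(utt_seed * 7919L %% .Machine$integer.max)
    noise <- stats::rnorm(length(clean$samples), 0, 1)
    noise <- noise / sqrt(mean(noise ^ 2)) * sigma   # exact RMS
    noisy <- wave_mono(clean$samples + noise, clean$fs)
    meta$snr_db[u] <- lev$active_db - rms_db(wave_mono(noise, clean$fs))
    mask <- optimal_mask(clean, mode = mode, snr_db = snr_db,
                         seed = utt_seed, cfg = cfg)
    C <- cochleagram(noisy)
    FW <- feature_windows(C)
    n_stft <- ncol(mask)
    map <- coch_to_stft_index(ncol(C$energies), C$hop, C$frame_len,
                              cfg, n_stft)
    n_coch <- ncol(C$energies)
    pick <- if (is.finite(windows_per_utt) && n_coch > windows_per_utt) {
      set.seed(utt_seed); sort(sample.int(n_coch, windows_per_utt))
    } else seq_len(n_coch)
    patch_of <- function(t) {
      cols <- pmin(pmax(t + (-2:2), 1), n_coch)
      as.numeric(mask[, map[cols], drop = FALSE])
    }
    feats[[u]] <- FW[pick, , drop = FALSE]
    targs[[u]] <- t(vapply(pick, patch_of, numeric(5 * nrow(mask))))
  }
  structure(list(features = do.call(rbind, feats),
                 targets = do.call(rbind, targs),
                 meta = meta),
            class = "mask_training_set")
}

#' Predict a TF mask from the mask-path beamformer output
#'
#' Runs the trained estimator over every 13-frame feature window; each
#' position yields a 129 x 5 patch and the up-to-five overlapping estimates
#' of every mask cell are averaged.  The mask (native cochleagram frame
#' rate, 12.8 ms hop) is then mapped to the 4-ms STFT grid by
#' nearest-frame-centre assignment.
#'
#' @param model A `mask_estimator` from [train_estimator()].
#' @param m_signal [wave_mono()] -- the time-domain M beamformer output.
#' @param n_frames_out Number of STFT frames of the target grid; defaults
#'   to the frame count of `stft(m_signal)`.
#' @param cfg [stft_config()].
#' @return Object of class `mask_estimate`: matrix `m` (129 x
#'   `n_frames_out`, values in [0, 1]).
#' @export
predict_mask <- function(model, m_signal, n_frames_out = NULL,
                         cfg = stft_config()) {
  stopifnot(inherits(model, "mask_estimator"), inherits(m_signal, "wave_mono"))
  C <- cochleagram(m_signal)
  FW <- feature_windows(C)
  Xs <- (t(FW) - model$mu) / model$sd
  P <- mlp_forward(model$layers, Xs)
  P <- P[[length(P)]]                             # 645 x positions
  n_coch <- ncol(P)
  n_bins <- model$n_bins
  acc <- matrix(0, n_bins, n_coch)
  cnt <- matrix(0, n_bins, n_coch)
  for (t in seq_len(n_coch)) {
    patch <- matrix(P[, t], n_bins, model$patch_frames)
    cols <- t + (-2:2)
    keep <- cols >= 1 & cols <= n_coch
    acc[, cols[keep]] <- acc[, cols[keep]] + patch[, keep]
    cnt[, cols[keep]] <- cnt[, cols[keep]] + 1
  }
  m_coch <- acc / cnt
  if (is.null(n_frames_out))
    n_frames_out <- ncol(stft(m_signal, cfg)$values)
  map <- coch_to_stft_index(n_coch, C$hop, C$frame_len, cfg, n_frames_out)
  # invert: nearest cochleagram frame for each STFT frame
  pad <- cfg$frame_len - cfg$hop
  stft_centre <- (seq_len(n_frames_out) - 1) * cfg$hop + cfg$frame_len / 2 - pad
  coch_centre <- (seq_len(n_coch) - 1) * C$hop + C$frame_len / 2
  nearest <- vapply(stft_centre, function(s)
    which.min(abs(coch_centre - s)), integer(1))
  m <- m_coch[, nearest, drop = FALSE]
  structure(list(m = pmin(pmax(m, 0), 1)), class = "mask_estimate")
}

#' Fit the two-component zero-mean complex-Gaussian speech prior
#'
#' EM fit of a two-component zero-mean circularly symmetric complex Gaussian
#' mixture to speech spectral amplitudes normalised by the P.56 active
#' speech level.  For zero-mean circular components the power `|z|^2` is
#' exponentially distributed with mean equal to the component variance, so
#' EM runs on the powers.
#'
#' @param x Clean speech: a [wave_mono()], a list of them (>= 60 s total
#'   recommended), or a raw complex vector of already-normalised spectral
#'   samples.
#' @param max_samples Subsample cap (default 2e5).
#' @param cfg [stft_config()].
#' @param seed Seed for subsampling.
#' @return Object of class `speech_prior_gmm`: `weights` and `variances`
#'   (ascending), component means identically zero.
#' @export
fit_speech_prior <- function(x, max_samples = 2e5, cfg = stft_config(),
                             seed = 1) {
  if (is.complex(x)) {
    z <- x
  } else {
    waves <- if (inherits(x, "wave_mono")) list(x) else x
    z <- unlist(lapply(waves, function(w) {
      lev <- active_speech_level(w)
      S <- stft(w, cfg)$values
      as.vector(S) / db2lin(lev$active_db)
    }))
  }
  p <- Mod(z) ^ 2
  p <- p[p > 0]
  if (length(p) > max_samples) {
    set.seed(seed)
    p <- p[sample.int(length(p), max_samples)]
  }
  em_fit <- function(v_init, w_init) {
    v <- v_init; w <- w_init
    ll_old <- -Inf
    for (it in seq_len(200)) {
      dens <- vapply(1:2, function(k) w[k] / v[k] * exp(-p / v[k]),
                     numeric(length(p)))
      tot <- rowSums(dens) + 1e-300
      r <- dens / tot
      w <- colMeans(r)
      if (any(w < 1e-4)) return(NULL)
      v <- colSums(r * p) / (colSums(r) + 1e-300)
      ll <- mean(log(tot))
      if (ll - ll_old < 1e-8) break
      ll_old <- ll
    }
    list(v = v, w = w)
  }
  m <- mean(p)
  fit <- em_fit(c(0.3 * m, 3 * m), c(0.5, 0.5))
  if (is.null(fit)) fit <- em_fit(c(0.1 * m, 1.5 * m), c(0.7, 0.3))
  if (is.null(fit)) stop("EM degenerated twice; is the corpus long enough?")
  ord <- order(fit$v)
  structure(list(weights = fit$w[ord], variances = fit$v[ord],
                 means = c(0, 0)),
            class = "speech_prior_gmm")
}

# Ephraim-Malah log-spectral-amplitude MMSE gain for a priori SNR xi and
# a posteriori SNR gamma: G = xi/(1+xi) * exp(0.5 * E1(v)), v = gamma*xi/(1+xi)
logmmse_gain <- function(xi, gam) {
  v <- pmax(gam * xi / (1 + xi), 1e-10)
  g <- xi / (1 + xi) * exp(0.5 * pracma::expint(v))
  pmin(g, 1e3)
}

#' Mask-conditioned mixture-prior log-MMSE gains
#'
#' The log-spectral-amplitude MMSE gain under the two-component speech
#' prior, with the mask value conditioning the component responsibilities:
#' the high-variance (speech-dominant) component receives responsibility
#' `m` and the low-variance component `1 - m`, giving
#' `g = G_hi^m * G_lo^(1-m)` (the mixture-weighted posterior mean of
#' `ln A`), clipped to `[g_floor, 1]`.
#'
#' @param Y A `spectrogram` (one ear's beamformer output).
#' @param mask A `mask_estimate` (or matrix in [0,1]) aligned with `Y`.
#' @param prior A `speech_prior_gmm`.
#' @param npsd A `noise_psd_track` (or noise-power matrix) aligned with `Y`.
#' @param g_floor Gain floor.
#' @return A `gain_field`.
#' @export
mask_informed_gains <- function(Y, mask, prior, npsd,
                                g_floor = db2lin(-30)) {
  stopifnot(inherits(Y, "spectrogram"), inherits(prior, "speech_prior_gmm"))
  m <- if (inherits(mask, "mask_estimate")) mask$m else mask
  lam <- if (inherits(npsd, "noise_psd_track")) npsd$lambda else npsd
  P <- Mod(Y$values) ^ 2
  if (!all(dim(m) == dim(P)) || !all(dim(lam) == dim(P)))
    stop("mask / noise PSD dimensions do not match Y")
  lev <- active_speech_level(istft(Y))
  s2 <- db2lin(lev$active_db) ^ 2                # de-normalisation factor
  lam <- pmax(lam, 1e-30)
  gam <- P / lam
  xi_lo <- prior$variances[1] * s2 / lam
  xi_hi <- prior$variances[2] * s2 / lam
  G_lo <- logmmse_gain(xi_lo, gam)
  G_hi <- logmmse_gain(xi_hi, gam)
  g <- exp(m * log(pmax(G_hi, 1e-10)) + (1 - m) * log(pmax(G_lo, 1e-10)))
  gain_field(g, g_floor)
}
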