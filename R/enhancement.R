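# Time-frequency gain computation for the Wiener and Kalman regimes,
# binaural gain linking, and orchestration of all enhancement regimes.

#' Gain field container
#'
#' @param g Real F x T matrix of TF gains.
#' @param g_floor Lower gain bound (default -30 dB).
#' @return Object of class `gain_field`; values clipped to
#'   `[g_floor, 1]`.
#' @export
gain_field <- function(g, g_floor = db2lin(-30)) {
  stopifnot(is.matrix(g), all(is.finite(g)))
  g <- pmin(pmax(g, g_floor), 1)   # g first: pmax/pmin keep arg-1 attributes
  structure(list(g = g, g_floor = g_floor), class = "gain_field")
}

#' Binaural gain linking
#'
#' Element-wise maximum of the left- and right-ear gain fields.  The larger
#' gain corresponds to the ear with the better local SNR; applying it to both
#' ears preserves interaural cues while approximately keeping the better
#' ear's enhancement.
#'
#' @param gL,gR `gain_field`s (or matrices) of equal dimensions.
#' @return A `gain_field`.
#' @export
link_gains <- function(gL, gR) {
  ml <- if (inherits(gL, "gain_field")) gL$g else gL
  mr <- if (inherits(gR, "gain_field")) gR$g else gR
  if (!all(dim(ml) == dim(mr))) stop("gain-field dimension mismatch")
  fl <- max(if (inherits(gL, "gain_field")) gL$g_floor else 0,
            if (inherits(gR, "gain_field")) gR$g_floor else 0)
  gain_field(pmax(ml, mr), g_floor = fl)
}

#' Speech-presence-probability noise PSD tracking
#'
#' MMSE noise periodogram tracking driven by a per-cell speech-presence
#' posterior under a fixed optimal prior SNR: the posterior probability of
#' speech presence given `|Y|^2` is computed with a fixed prior SNR
#' `xi_opt` and prior presence probability 0.5; the noise periodogram
#' estimate is `(1 - p)|Y|^2 + p * lambda(prev)` and is smoothed
#' recursively.  A stagnation guard caps the smoothed posterior at 0.99 so
#' the tracker cannot lock up during long speech stretches.
#'
#' @param Y A `spectrogram`.
#' @param prior_snr_db Fixed prior SNR in dB (default 15).
#' @param p_h1 Prior speech-presence probability (default 0.5).
#' @param alpha_psd Recursive PSD smoothing constant (default 0.8).
#' @param alpha_p Smoothing constant of the stagnation-guard SPP track.
#' @param init_frames Number of initial frames averaged for the starting
#'   noise PSD.
#' @return Object of class `noise_psd_track`: `lambda` (F x T noise power)
#'   and `spp` (F x T posterior in [0, 1]).
#' @export
spp_noise_psd <- function(Y, prior_snr_db = 15, p_h1 = 0.5, alpha_psd = 0.8,
                          alpha_p = 0.9, init_frames = 5) {
  stopifnot(inherits(Y, "spectrogram"))
  P <- Mod(Y$values) ^ 2
  n_bins <- nrow(P); n_frames <- ncol(P)
  xi <- 10 ^ (prior_snr_db / 10)
  # The fixed point of the raw MMSE update E[(1-p)Y + p*lambda] sits below
  # the true noise power because p rises with Y; compensate with the
  # model-implied constant E[1-p] / E[(1-p)U] for U ~ Exp(1) on the complex
  # bins and U ~ chi^2_1-normalised on the real DC/Nyquist bins.
  bias_c <- spp_bias_factor(xi, p_h1, real_bin = FALSE)
  bias_r <- spp_bias_factor(xi, p_h1, real_bin = TRUE)
  bias <- rep(bias_c, n_bins)
  bias[c(1L, n_bins)] <- bias_r
  lam <- matrix(0, n_bins, n_frames)
  spp <- matrix(0, n_bins, n_frames)
  lam_prev <- rowMeans(P[, seq_len(min(init_frames, n_frames)), drop = FALSE])
  lam_prev <- pmax(lam_prev, 1e-30)
  p_bar <- rep(p_h1, n_bins)
  prior_ratio <- (1 - p_h1) / p_h1
  for (t in seq_len(n_frames)) {
    y <- P[, t]
    loglr <- -log1p(xi) + y / lam_prev * xi / (1 + xi)
    loglr <- pmin(loglr, 700)
    p <- 1 / (1 + prior_ratio * exp(-loglr))
    p_bar <- alpha_p * p_bar + (1 - alpha_p) * p
    p[p_bar > 0.99] <- pmin(p[p_bar > 0.99], 0.99)
    lam_mmse <- (1 - p) * y * bias + p * lam_prev
    lam_prev <- alpha_psd * lam_prev + (1 - alpha_psd) * lam_mmse
    lam[, t] <- lam_prev
    spp[, t] <- p
  }
  structure(list(lambda = lam, spp = spp), class = "noise_psd_track")
}

# multiplicative correction making the SPP-weighted periodogram update
# unbiased under noise-only input (numeric integral over the normalised
# periodogram density: exponential for complex bins, chi^2_1 for DC/Nyquist)
spp_bias_factor <- function(xi, p_h1, real_bin = FALSE) {
  u <- seq(1e-4, 40, length.out = 8000)
  dens <- if (real_bin) stats::dchisq(u, df = 1) else exp(-u)
  p <- 1 / (1 + (1 - p_h1) / p_h1 * (1 + xi) * exp(-u * xi / (1 + xi)))
  mean_u <- if (real_bin) 1 else 1     # both normalised to unit mean
  num <- sum((1 - p) * dens) * mean_u
  den <- sum((1 - p) * u * dens)
  num / den
}

#' Wiener TF gains
#'
#' `g = (|Y|^2 - lambda_N) / |Y|^2`, clipped to `[g_floor, 1]`: the
#' estimated ratio of target power to noisy power in each TF region.
#'
#' @param Y A `spectrogram`.
#' @param npsd A `noise_psd_track` aligned with `Y` (or a noise-power
#'   matrix).
#' @param g_floor Gain floor (default -30 dB).
#' @return A `gain_field`.
#' @export
wiener_gains <- function(Y, npsd, g_floor = db2lin(-30)) {
  lam <- if (inherits(npsd, "noise_psd_track")) npsd$lambda else npsd
  P <- Mod(Y$values) ^ 2
  if (!all(dim(P) == dim(lam))) stop("noise PSD dimensions do not match Y")
  g <- (P - lam) / pmax(P, 1e-30)
  gain_field(g, g_floor)
}

# AR coefficient fit (Yule-Walker via least squares) on an amplitude window
fit_ar <- function(x, order) {
  n <- length(x)
  if (n < order + 4 || stats::sd(x) < 1e-12)
    return(list(a = c(1, rep(0, order - 1)), q = stats::var(x) + 1e-12))
  X <- sapply(seq_len(order), function(k) x[(order - k + 1):(n - k)])
  y <- x[(order + 1):n]
  fit <- tryCatch(stats::lm.fit(as.matrix(X), y), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients)))
    return(list(a = c(1, rep(0, order - 1)), q = stats::var(x) + 1e-12))
  a <- fit$coefficients
  # keep the companion matrix stable
  if (max(Mod(polyroot(rev(c(1, -a))))) > 1 / 1.01) a <- a * 0.98
  q <- max(mean(fit$residuals ^ 2), 1e-14)
  list(a = a, q = q)
}

#' Kalman (modulation-domain) TF gains
#'
#' Per frequency band, an AR model of the temporal evolution of the speech
#' amplitude envelope is tracked with a Kalman filter.  The observation is
#' the amplitude-domain spectral-subtraction estimate
#' `z = max(0, |Y| - sqrt(lambda_N))` with observation-noise variance
#' `lambda_N / 2`; AR coefficients and process noise are re-fit on a sliding
#' window of past posterior amplitudes.  The gain is
#' `clip(A_hat / |Y|, g_floor, 1)` with `A_hat` the posterior amplitude.
#'
#' @param Y A `spectrogram`.
#' @param npsd `noise_psd_track` (or noise-power matrix) aligned with `Y`.
#' @param g_floor Gain floor.
#' @param ar_order AR model order (default 2).
#' @param refit_every Frames between AR re-fits (default 32).
#' @param fit_window Length of the amplitude window used for fitting
#'   (default 64 frames).
#' @return A `gain_field`.
#' @export
kalman_gains <- function(Y, npsd, g_floor = db2lin(-30), ar_order = 2,
                         refit_every = 32, fit_window = 64) {
  lam <- if (inherits(npsd, "noise_psd_track")) npsd$lambda else npsd
  A_obs <- Mod(Y$values)
  if (!all(dim(A_obs) == dim(lam))) stop("noise PSD dimensions do not match Y")
  n_bins <- nrow(A_obs); n_frames <- ncol(A_obs)
  g <- matrix(g_floor, n_bins, n_frames)
  p <- ar_order
  for (k in seq_len(n_bins)) {
    y <- A_obs[k, ]
    lamk <- lam[k, ]
    z <- pmax(0, y - sqrt(lamk))
    init <- seq_len(min(8, n_frames))
    x <- rep(mean(z[init]), p)          # state: last p posterior amplitudes
    Pcov <- diag(p) * stats::var(z[init])
    if (!all(is.finite(Pcov))) Pcov <- diag(p)
    hist <- z[init]
    ar <- fit_ar(hist, p)
    H <- matrix(c(1, rep(0, p - 1)), 1, p)
    post <- numeric(n_frames)
    for (t in seq_len(n_frames)) {
      if (t %% refit_every == 0) {
        w0 <- max(1, t - fit_window)
        ar <- fit_ar(post[w0:(t - 1)], p)
      }
      FF <- rbind(ar$a, cbind(diag(p - 1), rep(0, p - 1)))
      x <- as.numeric(FF %*% x)
      Pcov <- FF %*% Pcov %*% t(FF)
      Pcov[1, 1] <- Pcov[1, 1] + ar$q
      r_obs <- lamk[t] / 2
      s <- Pcov[1, 1] + r_obs
      K <- Pcov[, 1] / max(s, 1e-30)
      innov <- z[t] - x[1]
      x <- x + K * innov
      x[1] <- max(0, x[1])
      Pcov <- Pcov - tcrossprod(K) * s
      # numerical guard: keep the covariance PSD
      ev_min <- min(diag(Pcov))
      if (!all(is.finite(Pcov)) || ev_min < 0) {
        Pcov <- diag(p) * max(abs(ev_min), 1e-12)
      }
      post[t] <- x[1]
      g[k, t] <- post[t] / max(y[t], 1e-30)
    }
  }
  gain_field(g, g_floor)
}

#' Run one enhancement regime on beamformer outputs
#'
#' Computes per-ear TF gains on the L and R spectrograms according to the
#' chosen regime, links them with [link_gains()] (element-wise maximum) and
#' applies the shared gain field to both ears.
#'
#' Regimes: `"none"` bypasses the gains; `"wiener"` and `"kalman"` estimate
#' the noise PSD per ear with [spp_noise_psd()] and call [wiener_gains()] /
#' [kalman_gains()]; `"mask"` predicts a TF mask from the M output with the
#' trained estimator in `ctx$model` and computes mixture-prior log-MMSE
#' gains (see [mask_informed_gains()]) with the speech prior `ctx$prior`.
#'
#' @param L,R,M `spectrogram`s from [apply_beamforming()].
#' @param regime `"none"`, `"mask"`, `"wiener"` or `"kalman"`.
#' @param ctx Context list; for `"mask"` it must contain `model` (from
#'   [train_estimator()]) and `prior` (from [fit_speech_prior()]).
#' @param g_floor Gain floor.
#' @return List: `le`, `re` ([wave_mono()]s) and `gain` (the linked
#'   `gain_field`, `NULL` for regime `"none"`).
#' @export
enhance <- function(L, R, M, regime = c("none", "mask", "wiener", "kalman"),
                    ctx = list(), g_floor = db2lin(-30)) {
  regime <- match.arg(regime)
  if (regime == "none") {
    return(list(le = istft(L), re = istft(R), gain = NULL))
  }
  ear_gain <- switch(
    regime,
    wiener = function(S) wiener_gains(S, spp_noise_psd(S), g_floor),
    kalman = function(S) kalman_gains(S, spp_noise_psd(S), g_floor),
    mask = {
      if (is.null(ctx$model) || is.null(ctx$prior))
        stop("regime 'mask' needs ctx$model and ctx$prior")
      mask <- predict_mask(ctx$model, istft(M), n_frames_out = ncol(L$values))
      function(S) mask_informed_gains(S, mask, ctx$prior,
                                      spp_noise_psd(S), g_floor)
    })
  g <- link_gains(ear_gain(L), ear_gain(R))
  out <- apply_gain_field(L, R, g)
  list(le = out$le, re = out$re, gain = g)
}
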