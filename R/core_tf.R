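# STFT analysis/synthesis engine, level measurement and TF-gain application.
# All processing stages share one STFT grid: 16 ms frames, 75% overlap, so at
# 16 kHz each TF cell is 4 ms x 62.5 Hz and there are 129 frequency bins.

#' Monophonic waveform container
#'
#' A lightweight container for a single-channel pressure waveform expressed
#' relative to digital full scale.  The package-wide calibration convention is
#' that an RMS of 1.0 corresponds to 94 dB SPL (see [spl_to_dbfs()]).
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sample rate in Hz (positive scalar).
#' @return An object of class `wave_mono` with elements `samples` and `fs`.
#' @export
wave_mono <- function(samples, fs) {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0, all(is.finite(samples)))
  structure(list(samples = samples, fs = fs), class = "wave_mono")
}

#' @export
length.wave_mono <- function(x) length(x$samples)

#' @export
print.wave_mono <- function(x, ...) {
  cat(sprintf("<wave_mono: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

as_wave <- function(x, fs) {
  if (inherits(x, "wave_mono")) x else wave_mono(x, fs)
}

#' STFT configuration
#'
#' @param frame_len_ms Frame duration in milliseconds.  Default 16 ms.
#' @param overlap_frac Fractional frame overlap.  Default 0.75.
#' @param fs Sample rate in Hz.  Default 16000.
#' @param window Analysis/synthesis window identifier; only `"sqrthann"`
#'   (square-root periodic Hann on both sides, WOLA) is implemented.
#' @return An object of class `stft_config` with derived fields
#'   `frame_len` (samples), `hop` (samples) and `n_bins`.
#' @export
stft_config <- function(frame_len_ms = 16, overlap_frac = 0.75, fs = 16000,
                        window = "sqrthann") {
  stopifnot(frame_len_ms > 0, overlap_frac >= 0, overlap_frac < 1, fs > 0)
  window <- match.arg(window, "sqrthann")
  frame_len <- round(fs * frame_len_ms / 1000)
  if (frame_len %% 2L != 0L)
    stop("frame length in samples must be even (got ", frame_len, ")")
  hop <- round(frame_len * (1 - overlap_frac))
  stopifnot(hop >= 1)
  structure(list(frame_len_ms = frame_len_ms, overlap_frac = overlap_frac,
                 fs = fs, window = window,
                 frame_len = as.integer(frame_len), hop = as.integer(hop),
                 n_bins = as.integer(frame_len / 2 + 1)),
            class = "stft_config")
}

# periodic Hann; its square root is used on both analysis and synthesis side
# so the product overlap-adds to a constant at 75% overlap (COLA).
sqrt_hann_window <- function(n) {
  sqrt(0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)))
}

#' Short-time Fourier transform
#'
#' Frames the signal with a square-root Hann analysis window and returns the
#' one-sided complex spectrum per frame.  The signal is zero-padded internally
#' by `frame_len - hop` samples on each side so that every true sample has
#' full window overlap; [istft()] trims the padding again, which makes the
#' analysis/synthesis pair perfectly reconstructing (to machine precision)
#' over the whole signal including its edges.
#'
#' @param x A [wave_mono()] (or numeric vector if `fs` matches `cfg`).
#' @param cfg An [stft_config()]; its `fs` must match the waveform's.
#' @return An object of class `spectrogram`: complex matrix `values`
#'   (`n_bins` x frames), the `cfg`, and bookkeeping needed for inversion.
#' @export
stft <- function(x, cfg = stft_config()) {
  x <- as_wave(x, cfg$fs)
  if (x$fs != cfg$fs) stop("sample-rate mismatch between waveform and config")
  n <- length(x$samples)
  frame <- cfg$frame_len
  hop <- cfg$hop
  if (n < frame) stop("signal shorter than one STFT frame (", frame, " samples)")
  pad <- frame - hop
  n_pad <- n + 2L * pad
  n_frames <- as.integer(ceiling((n_pad - frame) / hop) + 1)
  total <- (n_frames - 1L) * hop + frame
  xp <- c(rep(0, pad), x$samples, rep(0, total - n - pad))
  w <- sqrt_hann_window(frame)
  idx <- outer(seq_len(frame), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(xp[idx], nrow = frame) * w
  spec <- stats::mvfft(frames)[seq_len(cfg$n_bins), , drop = FALSE]
  structure(list(values = spec, cfg = cfg, n_samples = n, pad = pad),
            class = "spectrogram")
}

#' @export
dim.spectrogram <- function(x) dim(x$values)

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d bins x %d frames, fs %g Hz, frame %d / hop %d>\n",
              nrow(x$values), ncol(x$values), x$cfg$fs,
              x$cfg$frame_len, x$cfg$hop))
  invisible(x)
}

#' Inverse STFT (weighted overlap-add)
#'
#' @param S A `spectrogram` from [stft()], possibly with modified `values`.
#' @param length_out Output length in samples; defaults to the length of the
#'   analysed signal recorded in `S`.
#' @return A [wave_mono()].
#' @export
istft <- function(S, length_out = NULL) {
  stopifnot(inherits(S, "spectrogram"))
  cfg <- S$cfg
  if (nrow(S$values) != cfg$n_bins)
    stop("spectrogram rows inconsistent with config (expected ",
         cfg$n_bins, ", got ", nrow(S$values), ")")
  frame <- cfg$frame_len
  hop <- cfg$hop
  n_frames <- ncol(S$values)
  # rebuild the two-sided spectrum by conjugate symmetry
  full <- rbind(S$values,
                Conj(S$values[seq(cfg$n_bins - 1L, 2L), , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / frame
  w <- sqrt_hann_window(frame)
  frames <- frames * w
  total <- (n_frames - 1L) * hop + frame
  y <- numeric(total)
  wsum <- numeric(total)
  w2 <- w * w
  for (m in seq_len(n_frames)) {
    sl <- ((m - 1L) * hop + 1L):((m - 1L) * hop + frame)
    y[sl] <- y[sl] + frames[, m]
    wsum[sl] <- wsum[sl] + w2
  }
  nz <- wsum > 1e-12
  y[nz] <- y[nz] / wsum[nz]
  if (is.null(length_out)) length_out <- S$n_samples
  pad <- if (is.null(S$pad)) 0L else S$pad
  out <- y[(pad + 1L):(pad + length_out)]
  wave_mono(out, cfg$fs)
}

#' Decibel helpers
#'
#' `lin2db()`/`db2lin()` convert amplitude ratios; `rms_db()` reports the RMS
#' level of a waveform in dB relative to full scale; `spl_to_dbfs()` maps a
#' sound pressure level to the package's digital convention (RMS 1.0 = 94 dB
#' SPL, so 65 dB SPL = -29 dBFS).
#'
#' @param a Amplitude ratio.
#' @param d Level in dB.
#' @param x A [wave_mono()] or numeric vector.
#' @param spl Level in dB SPL.
#' @name db-helpers
NULL

#' @rdname db-helpers
#' @export
lin2db <- function(a) 20 * log10(a)

#' @rdname db-helpers
#' @export
db2lin <- function(d) 10 ^ (d / 20)

#' @rdname db-helpers
#' @export
rms_db <- function(x) {
  s <- if (inherits(x, "wave_mono")) x$samples else x
  20 * log10(sqrt(mean(s ^ 2)))
}

#' @rdname db-helpers
#' @export
spl_to_dbfs <- function(spl) spl - 94

#' Active speech level (P.56-style)
#'
#' Iterative envelope/threshold estimate of the active speech level: the
#' signal envelope (exponentially smoothed rectified amplitude, 30 ms time
#' constant) is compared against a margin 15.9 dB below the candidate active
#' level; the active level is recomputed from the energy of the active
#' samples until it changes by less than 0.1 dB (at most 30 iterations).
#'
#' @param x A [wave_mono()].
#' @param margin_db Activity margin below the active level.  Default 15.9 dB.
#' @param tau_ms Envelope smoothing time constant.  Default 30 ms.
#' @return A list of class `level_report`: `rms_db`, `active_db`,
#'   `activity_frac`.  For an all-zero signal `activity_frac` is 0 and
#'   `active_db` is `-Inf` (flag sentinel).
#' @export
active_speech_level <- function(x, margin_db = 15.9, tau_ms = 30) {
  stopifnot(inherits(x, "wave_mono"), length(x$samples) > 0)
  s <- x$samples
  if (all(s == 0)) {
    return(structure(list(rms_db = -Inf, active_db = -Inf, activity_frac = 0),
                     class = "level_report"))
  }
  overall_rms <- sqrt(mean(s ^ 2))
  alpha <- exp(-1 / (tau_ms / 1000 * x$fs))
  env <- as.numeric(stats::filter(abs(s), alpha, method = "recursive")) *
    (1 - alpha)
  active_lin <- overall_rms
  for (i in seq_len(30)) {
    thr <- active_lin * db2lin(-margin_db)
    act <- env > thr
    if (!any(act)) break
    new_lin <- sqrt(mean(s[act] ^ 2))
    if (abs(lin2db(new_lin) - lin2db(active_lin)) < 0.1) {
      active_lin <- new_lin
      break
    }
    active_lin <- new_lin
  }
  thr <- active_lin * db2lin(-margin_db)
  act <- env > thr
  structure(list(rms_db = lin2db(overall_rms),
                 active_db = lin2db(sqrt(mean(s[act] ^ 2))),
                 activity_frac = mean(act)),
            class = "level_report")
}

#' Apply one TF gain field to both ears
#'
#' Multiplies the left and right spectrograms element-wise by the same real
#' gain matrix and resynthesises both ears.  Using one shared gain field is
#' what preserves interaural cues: the interaural magnitude ratio and phase
#' of every TF cell are unchanged.
#'
#' @param L,R `spectrogram` objects of equal dimensions.
#' @param G Real gain matrix with the same dimensions (a `gain_field` or
#'   plain matrix).
#' @return A list with [wave_mono()] elements `le` and `re`.
#' @export
apply_gain_field <- function(L, R, G) {
  stopifnot(inherits(L, "spectrogram"), inherits(R, "spectrogram"))
  g <- if (inherits(G, "gain_field")) G$g else G
  if (!all(dim(L$values) == dim(g)) || !all(dim(R$values) == dim(g)))
    stop("gain-field dimensions do not match the spectrograms")
  Lg <- L; Lg$values <- L$values * g
  Rg <- R; Rg$values <- R$values * g
  list(le = istft(Lg), re = istft(Rg))
}
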