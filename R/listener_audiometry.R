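# NAL-R hearing-loss compensation and parametric simulated listeners.

AUDIOGRAM_FREQS <- c(250, 500, 1000, 2000, 3000, 4000, 6000)
NALR_C <- c(`250` = -17, `500` = -8, `1000` = 1, `2000` = -1,
            `3000` = -2, `4000` = -2, `6000` = -2)

#' Audiogram
#'
#' @param thresholds Named numeric vector of pure-tone thresholds in dB HL
#'   at (a subset of) 250, 500, 1000, 2000, 3000, 4000, 6000 Hz.  Missing
#'   frequencies are interpolated (with a warning) when gains are computed.
#' @return Object of class `audiogram`.
#' @export
audiogram <- function(thresholds) {
  f <- as.numeric(names(thresholds))
  stopifnot(all(f %in% AUDIOGRAM_FREQS),
            all(thresholds >= -10), all(thresholds <= 120))
  structure(list(freqs = f, thresholds = as.numeric(thresholds)),
            class = "audiogram")
}

#' Read audiograms from CSV
#'
#' Expected columns: `ear` ("left"/"right"), `frequency_hz`,
#' `threshold_db_hl`.
#'
#' @param path CSV path.
#' @return Named list of [audiogram()]s, one per ear.
#' @export
read_audiogram_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("ear", "frequency_hz", "threshold_db_hl") %in% names(d)))
  out <- lapply(split(d, d$ear), function(e) {
    th <- e$threshold_db_hl
    names(th) <- e$frequency_hz
    audiogram(th)
  })
  out
}

#' NAL-R insertion gains
#'
#' The NAL-R linear prescription: with
#' `X = 0.05 (H500 + H1000 + H2000)`, the insertion gain at frequency f is
#' `max(0, X + 0.31 H(f) + C(f))` with the frequency constants
#' C = (-17, -8, +1, -1, -2, -2, -2) dB at (250, 500, 1k, 2k, 3k, 4k, 6k) Hz.
#'
#' @param a An [audiogram()].
#' @return Object of class `fitting_gains`: `freqs`, `gains_db` (floored at
#'   0), and `x_factor`.
#' @export
nalr_gains <- function(a) {
  stopifnot(inherits(a, "audiogram"))
  H <- a$thresholds
  names(H) <- a$freqs
  missing <- setdiff(AUDIOGRAM_FREQS, a$freqs)
  if (length(missing) > 0) {
    warning("interpolating audiogram at ",
            paste(missing, collapse = ", "), " Hz")
    Hi <- stats::approx(log(a$freqs), a$thresholds, xout = log(AUDIOGRAM_FREQS),
                        rule = 2)$y
    H <- Hi
    names(H) <- AUDIOGRAM_FREQS
  }
  X <- 0.05 * (H["500"] + H["1000"] + H["2000"])
  gains <- pmax(0, X + 0.31 * H + NALR_C[as.character(AUDIOGRAM_FREQS)])
  structure(list(freqs = AUDIOGRAM_FREQS, gains_db = unname(gains),
                 x_factor = unname(X)),
            class = "fitting_gains")
}

#' Apply fitting gains to a waveform
#'
#' Linear-phase FIR compensation: the prescribed gains are interpolated
#' (linearly on a log-frequency axis, held flat outside the audiogram
#' range) onto a dense frequency grid, a zero-phase frequency-sampled FIR
#' is built, and the filter delay is compensated so the output is aligned
#' with the input.
#'
#' @param x A [wave_mono()] at 16 kHz.
#' @param fit A `fitting_gains` object (or a named list with `freqs`,
#'   `gains_db` for arbitrary gain curves).
#' @param n_taps FIR length (even; default 512).
#' @return A [wave_mono()] of the same length.
#' @export
apply_fitting <- function(x, fit, n_taps = 512) {
  stopifnot(inherits(x, "wave_mono"), x$fs == 16000, n_taps %% 2 == 0)
  fgrid <- seq(0, x$fs / 2, length.out = n_taps / 2 + 1)
  lg <- log(pmax(fgrid, 1))
  g_db <- stats::approx(log(fit$freqs), fit$gains_db, xout = lg,
                        rule = 2)$y
  H <- db2lin(g_db)
  Hfull <- c(H, rev(H[2:(n_taps / 2)]))
  h <- Re(stats::fft(Hfull, inverse = TRUE)) / n_taps
  h <- c(h[(n_taps / 2 + 1):n_taps], h[1:(n_taps / 2)])   # linear phase
  w <- 0.5 * (1 - cos(2 * pi * (0:(n_taps - 1)) / (n_taps - 1)))
  h <- h * w
  y <- fft_conv(x$samples, h)
  delay <- n_taps / 2
  wave_mono(y[(delay + 1):(delay + length(x$samples))], x$fs)
}

#' Simulated listener
#'
#' A parametric psychometric listener: the probability of identifying a
#' keyword at a given SNR is `plogis((snr - true_srt) * 4 * slope)`, which
#' equals 0.5 at `true_srt` and has derivative `slope` (probability per dB)
#' at that midpoint.
#'
#' @param true_srt The listener's true 50%-correct SNR in dB.
#' @param slope Psychometric slope at the midpoint (probability/dB,
#'   default 0.15).
#' @return Object of class `listener_model`.
#' @export
listener_model <- function(true_srt, slope = 0.15) {
  stopifnot(slope > 0)
  structure(list(true_srt = true_srt, slope = slope),
            class = "listener_model")
}

#' Probability of a correct keyword at a given SNR
#'
#' @param lm A [listener_model()].
#' @param snr_db Presentation SNR.
#' @export
keyword_prob <- function(lm, snr_db) {
  stats::plogis((snr_db - lm$true_srt) * 4 * lm$slope)
}

#' Simulated keyword scoring for one sentence
#'
#' Draws the number of correctly identified keywords from
#' `Binomial(n_keywords, p)` with `p` from [keyword_prob()].
#'
#' @param lm A [listener_model()].
#' @param snr_db Presentation SNR in dB.
#' @param n_keywords Keywords per sentence (default 5).
#' @return Integer count in `[0, n_keywords]`.
#' @export
keyword_response <- function(lm, snr_db, n_keywords = 5) {
  stopifnot(n_keywords >= 1)
  stats::rbinom(1, n_keywords, keyword_prob(lm, snr_db))
}
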