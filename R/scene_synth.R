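# Synthetic-scene generator: a rigid-sphere head with a two-microphone BTE
# device on each ear, fractional-delay direct paths with head shadow, optional
# exponentially decaying diffuse reverberant tails, speech-shaped / babble
# noise, slow AGC level equalisation, SNR level rules and trial assembly.

SPEED_OF_SOUND <- 343  # m/s

mic_names <- function() c("lf", "lb", "rf", "rb")

#' Four-microphone frame
#'
#' Synchronised waveforms from the four hearing-aid microphones: left front
#' (LF), left back (LB), right front (RF), right back (RB).
#'
#' @param lf,lb,rf,rb [wave_mono()] objects of equal length and sample rate.
#' @return Object of class `mic_frame`.
#' @export
mic_frame <- function(lf, lb, rf, rb) {
  chans <- list(lf = lf, lb = lb, rf = rf, rb = rb)
  fs <- unique(vapply(chans, function(w) w$fs, numeric(1)))
  len <- unique(vapply(chans, function(w) length(w$samples), numeric(1)))
  if (length(fs) != 1 || length(len) != 1)
    stop("all four channels must share sample rate and length")
  structure(chans, class = "mic_frame")
}

#' @export
print.mic_frame <- function(x, ...) {
  cat(sprintf("<mic_frame: 4 channels x %d samples @ %g Hz>\n",
              length(x$lf$samples), x$lf$fs))
  invisible(x)
}

mic_matrix <- function(mics) {
  vapply(mic_names(), function(ch) mics[[ch]]$samples,
         numeric(length(mics$lf$samples)))
}

mic_apply <- function(mics, f) {
  do.call(mic_frame, lapply(mics[mic_names()], f))
}

mic_scale <- function(mics, a) {
  mic_apply(mics, function(w) wave_mono(w$samples * a, w$fs))
}

mic_add <- function(a, b) {
  mic_frame(wave_mono(a$lf$samples + b$lf$samples, a$lf$fs),
            wave_mono(a$lb$samples + b$lb$samples, a$lb$fs),
            wave_mono(a$rf$samples + b$rf$samples, a$rf$fs),
            wave_mono(a$rb$samples + b$rb$samples, a$rb$fs))
}

#' BTE array geometry
#'
#' Microphone coordinates for a front/back pair on each ear of a spherical
#' head.  Axes: x to the listener's right, y to the front, z up; origin at the
#' head centre.
#'
#' @param head_radius Head radius in metres (default 0.0875 m).
#' @param mic_spacing Front-to-back microphone spacing on each device in
#'   metres (default 0.015 m).
#' @return Object of class `array_geometry` with a 4 x 3 `mic_positions`
#'   matrix (rows LF, LB, RF, RB) and `head_radius`.
#' @export
bte_array_geometry <- function(head_radius = 0.0875, mic_spacing = 0.015) {
  stopifnot(head_radius > 0, mic_spacing > 0.004, mic_spacing < 0.03)
  h <- mic_spacing / 2
  pos <- rbind(lf = c(-head_radius,  h, 0),
               lb = c(-head_radius, -h, 0),
               rf = c( head_radius,  h, 0),
               rb = c( head_radius, -h, 0))
  colnames(pos) <- c("x", "y", "z")
  structure(list(mic_positions = pos, head_radius = head_radius,
                 mic_spacing = mic_spacing),
            class = "array_geometry")
}

#' Scene specification
#'
#' @param target_azimuth Target azimuth in degrees (0 = front, positive =
#'   right).
#' @param noise_azimuth Noise azimuth in degrees, or `"diffuse"` for an
#'   isotropic multi-direction noise field.
#' @param t60 Reverberation time in seconds; 0 means anechoic.
#' @param source_distance Source distance in metres.
#' @param drr_db Direct-to-reverberant ratio in dB (ignored when `t60 = 0`).
#' @param seed Integer seed controlling all stochastic components.
#' @export
scene_spec <- function(target_azimuth = 0, noise_azimuth = 0, t60 = 0,
                       source_distance = 1.5, drr_db = 2, seed = 1) {
  stopifnot(t60 >= 0, source_distance > 0.2)
  structure(list(target_azimuth = target_azimuth,
                 noise_azimuth = noise_azimuth, t60 = t60,
                 source_distance = source_distance, drr_db = drr_db,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Classroom scene preset
#'
#' Reverberant, diffuse-noise preset (t60 = 0.42 s) with `"middle"` and
#' `"corner"` listener locations that differ by 3 dB in direct-to-reverberant
#' ratio.
#'
#' @param location `"middle"` or `"corner"`.
#' @param seed Integer seed.
#' @export
classroom_scene <- function(location = c("middle", "corner"), seed = 1) {
  location <- match.arg(location)
  drr <- if (location == "middle") 2 else -1
  scene_spec(target_azimuth = 0, noise_azimuth = "diffuse", t60 = 0.42,
             source_distance = if (location == "middle") 2.5 else 4,
             drr_db = drr, seed = seed)
}

# windowed-sinc fractional delay kernel of length n_taps placed at `delay`
# samples (delay may be fractional, must leave room inside the kernel)
frac_delay_kernel <- function(delay, n_taps) {
  n <- 0:(n_taps - 1)
  h <- sinc_fn(n - delay)
  # Hann taper centred on the delay to control sinc truncation
  half <- n_taps / 2
  taper <- 0.5 * (1 + cos(pi * pmin(1, abs(n - delay) / half)))
  h * taper
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# one-pole low-pass (head shadow) applied to an impulse response
one_pole_lp <- function(h, fc, fs) {
  b <- 1 - exp(-2 * pi * fc / fs)
  as.numeric(stats::filter(h * b, 1 - b, method = "recursive"))
}

#' Simulate BTE impulse responses for one source
#'
#' Direct path: per-microphone fractional delays from a rigid-sphere
#' (Woodworth) path-length model with 1/r attenuation and a first-order
#' head-shadow low-pass on the far (acoustically shadowed) ear.  If
#' `t60 > 0`, an exponentially decaying diffuse tail is appended, independent
#' across microphones apart from a low-frequency common component that shapes
#' interaural coherence towards the ideal diffuse-field sinc curve below
#' about 1 kHz; tail energy is set by the scene's direct-to-reverberant
#' ratio.
#'
#' @param geom An [bte_array_geometry()].
#' @param azimuth Source azimuth in degrees (0 front, positive right).
#' @param distance Source distance in metres.
#' @param t60 Reverberation time (s); 0 for anechoic.
#' @param drr_db Direct-to-reverberant ratio (dB) when `t60 > 0`.
#' @param fs Sample rate (Hz).
#' @param seed Seed for the diffuse tail.
#' @return Object of class `ir_set`: list `irs` of 4 numeric impulse
#'   responses named lf/lb/rf/rb, plus `fs` and per-mic direct `delays`
#'   (samples).
#' @export
simulate_brirs <- function(geom, azimuth, distance, t60 = 0, drr_db = 2,
                           fs = 16000, seed = 1) {
  stopifnot(inherits(geom, "array_geometry"))
  a <- geom$head_radius
  r <- distance
  if (r <= a) stop("source must lie outside the head")
  th <- azimuth * pi / 180
  src_dir <- c(sin(th), cos(th), 0)             # unit vector towards source
  ear_angle <- c(lf = -pi / 2, lb = -pi / 2, rf = pi / 2, rb = pi / 2)
  los_limit <- acos(a / r)
  delays <- numeric(4); names(delays) <- mic_names()
  shadowed <- logical(4); names(shadowed) <- mic_names()
  gamma_all <- numeric(4); names(gamma_all) <- mic_names()
  for (ch in mic_names()) {
    gam <- abs(atan2(sin(th - ear_angle[ch]), cos(th - ear_angle[ch])))
    gamma_all[ch] <- gam
    path <- if (gam <= los_limit) {
      sqrt(r ^ 2 + a ^ 2 - 2 * r * a * cos(gam))
    } else {
      sqrt(r ^ 2 - a ^ 2) + a * (gam - los_limit)
    }
    shadowed[ch] <- gam > pi / 2
    # small front/back offset projected on the propagation direction
    p <- geom$mic_positions[ch, ]
    p_offset <- c(0, p["y"], 0)
    delays[ch] <- (path - sum(p_offset * src_dir)) / SPEED_OF_SOUND * fs
  }
  base_delay <- min(delays)
  rel <- delays - base_delay + 8          # leave room for the sinc pre-ring
  n_direct <- as.integer(ceiling(max(rel)) + 48)
  irs <- lapply(mic_names(), function(ch) {
    h <- frac_delay_kernel(rel[ch], n_direct) / r
    if (shadowed[ch]) {
      fc <- max(800, 8000 * (1 + cos(gamma_all[ch])))
      h <- one_pole_lp(h, fc, fs)
    }
    h
  })
  names(irs) <- mic_names()
  if (t60 > 0) {
    set.seed(seed)
    nt <- as.integer(round(1.2 * t60 * fs))
    env <- exp(-6.9078 * (seq_len(nt) - 1) / (t60 * fs))
    common <- stats::rnorm(nt)
    d_ears <- 2 * a
    f <- seq(0, fs / 2, length.out = floor(nt / 2) + 1)
    coh <- pmax(0, sinc_fn(2 * f * d_ears / SPEED_OF_SOUND))
    wc <- sqrt(coh); wi <- sqrt(1 - coh)
    mix_coherent <- function(x_common, x_indep) {
      n2 <- length(f)
      Xc <- stats::fft(x_common); Xi <- stats::fft(x_indep)
      wfull <- c(wc, rev(wc[2:(n2 - 1)]))
      wifull <- c(wi, rev(wi[2:(n2 - 1)]))
      if (length(wfull) < nt) { wfull <- c(wfull, wc[n2]); wifull <- c(wifull, wi[n2]) }
      Re(stats::fft(Xc * wfull[seq_len(nt)] + Xi * wifull[seq_len(nt)],
                    inverse = TRUE)) / nt
    }
    direct_energy <- vapply(irs, function(h) sum(h ^ 2), numeric(1))
    tail_energy_target <- mean(direct_energy) / 10 ^ (drr_db / 10)
    gap <- n_direct  # tail starts right after the direct part
    irs <- lapply(mic_names(), function(ch) {
      indep <- stats::rnorm(nt)
      tail <- mix_coherent(common, indep) * env
      tail <- tail * sqrt(tail_energy_target / sum(tail ^ 2))
      c(irs[[ch]], tail)
    })
    names(irs) <- mic_names()
  }
  structure(list(irs = irs, fs = fs, delays = delays, t60 = t60),
            class = "ir_set")
}

fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, 2)
  X <- stats::fft(c(x, rep(0, nf - length(x))))
  H <- stats::fft(c(h, rep(0, nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE) / nf)[seq_len(n)]
}

#' Render a source through an impulse-response set
#'
#' Convolves a mono source with each microphone's impulse response.
#'
#' @param src A [wave_mono()].
#' @param irs An `ir_set` from [simulate_brirs()].
#' @return A [mic_frame()] of common length `length(src) + max ir length - 1`.
#' @export
render_scene <- function(src, irs) {
  stopifnot(inherits(src, "wave_mono"), inherits(irs, "ir_set"))
  if (src$fs != irs$fs) stop("sample-rate mismatch between source and IRs")
  max_len <- max(vapply(irs$irs, length, integer(1)))
  out_len <- length(src$samples) + max_len - 1L
  chans <- lapply(irs$irs, function(h) {
    y <- fft_conv(src$samples, h)
    wave_mono(c(y, rep(0, out_len - length(y))), src$fs)
  })
  do.call(mic_frame, chans[mic_names()])
}

# moving average of a PSD over a constant fractional-octave width
smooth_fractional_octave <- function(psd, f, width_oct = 1 / 3) {
  out <- psd
  half <- 2 ^ (width_oct / 2)
  for (i in seq_along(f)) {
    if (f[i] <= 0) next
    sel <- f >= f[i] / half & f <= f[i] * half
    out[i] <- mean(psd[sel])
  }
  out
}

# Welch one-sided amplitude spectrum (512-point Hann, 50% overlap)
welch_spectrum <- function(x, fs, nfft = 512) {
  hop <- nfft / 2
  n <- length(x)
  if (n < nfft) stop("signal too short for spectrum estimation")
  w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
  n_frames <- floor((n - nfft) / hop) + 1
  acc <- numeric(nfft / 2 + 1)
  for (m in seq_len(n_frames)) {
    seg <- x[((m - 1) * hop + 1):((m - 1) * hop + nfft)] * w
    X <- stats::fft(seg)[1:(nfft / 2 + 1)]
    acc <- acc + Mod(X) ^ 2
  }
  list(psd = acc / n_frames, f = seq(0, fs / 2, length.out = nfft / 2 + 1))
}

#' Generate speech-shaped or babble noise
#'
#' Mode `"ssn"` filters Gaussian noise so that its long-term spectrum matches
#' the average spectrum of the reference speech.  Mode `"babble"` sums
#' `n_streams >= 6` independently and slowly amplitude-modulated SSN streams,
#' giving a nonstationary classroom-like surrogate.
#'
#' @param mode `"ssn"` or `"babble"`.
#' @param ref_speech Reference speech [wave_mono()] whose long-term spectrum
#'   is matched.
#' @param duration_s Duration in seconds (> 0).
#' @param seed Integer seed.
#' @param n_streams Number of babble streams (>= 6).
#' @return A [wave_mono()] with RMS matched to `ref_speech`.
#' @export
make_noise <- function(mode = c("ssn", "babble"), ref_speech, duration_s,
                       seed = 1, n_streams = 6) {
  mode <- match.arg(mode)
  stopifnot(duration_s > 0, inherits(ref_speech, "wave_mono"))
  if (mode == "babble" && n_streams < 6) stop("babble needs >= 6 streams")
  fs <- ref_speech$fs
  n <- as.integer(round(duration_s * fs))
  sp <- welch_spectrum(ref_speech$samples, fs)
  # long-term average spectrum: fractional-octave smoothing bridges the
  # harmonic fine structure of any single reference utterance
  mag <- sqrt(smooth_fractional_octave(sp$psd, sp$f, width_oct = 1 / 3))
  set.seed(seed)
  one_stream <- function() {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    fgrid <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
    H_half <- stats::approx(sp$f, mag, xout = fgrid, rule = 2)$y
    H <- c(H_half, rev(H_half[2:(length(H_half) - 1 + n %% 2)]))
    Re(stats::fft(X * H[seq_len(n)], inverse = TRUE)) / n
  }
  y <- if (mode == "ssn") {
    one_stream()
  } else {
    acc <- numeric(n)
    t_env <- seq_len(n)
    for (k in seq_len(n_streams)) {
      s <- one_stream()
      # slow (~2-8 Hz) log-normal envelope
      z <- stats::rnorm(ceiling(duration_s * 8) + 2)
      env <- stats::approx(seq_along(z), z,
                           xout = 1 + (t_env - 1) / fs * 8, rule = 2)$y
      acc <- acc + s * exp(0.7 * env)
    }
    acc
  }
  y <- y * sqrt(mean(ref_speech$samples ^ 2) / mean(y ^ 2))
  wave_mono(y, fs)
}

#' Slow AGC level equalisation across the four microphones
#'
#' Computes each microphone's log-energy envelope with a sliding rectangular
#' 1-s window, averages the envelopes (in log energy) across the four
#' microphones, and applies the gain `mean(envelope) - envelope(t)`,
#' identical on all four channels.  The window is centred, so the gain at
#' time t uses half a window (0.5 s) of look-ahead.
#'
#' @param mics A [mic_frame()] longer than `window_s`.
#' @param window_s Envelope window length in seconds (default 1).
#' @return List: `mics` (equalised [mic_frame()]) and `gain_db` (per-sample
#'   applied gain track, dB on energy).
#' @export
agc_equalize <- function(mics, window_s = 1) {
  stopifnot(inherits(mics, "mic_frame"))
  fs <- mics$lf$fs
  n <- length(mics$lf$samples)
  W <- as.integer(round(window_s * fs))
  if (n <= W) stop("input must be longer than the AGC window")
  half <- W %/% 2
  moving_energy <- function(x) {
    cs <- c(0, cumsum(x ^ 2))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  logenv <- vapply(mic_names(),
                   function(ch) 10 * log10(moving_energy(mics[[ch]]$samples) + 1e-30),
                   numeric(n))
  avg_env <- rowMeans(logenv)
  gain_db <- mean(avg_env) - avg_env
  g <- 10 ^ (gain_db / 20)
  out <- mic_apply(mics, function(w) wave_mono(w$samples * g, w$fs))
  list(mics = out, gain_db = gain_db)
}

#' Set presentation levels for a nominal SNR
#'
#' Applies the asymmetric level rule: at 0 dB SNR both target and masker sit
#' at 65 dB SPL; for negative SNRs the masker stays at 65 dB SPL and the
#' target is attenuated; for positive SNRs the target stays at 65 dB SPL and
#' the masker is attenuated.  Target level is the P.56 active speech level
#' and masker level the RMS, both measured at the reference front microphone
#' (the front microphone of the ear nearer the noise-free side).
#'
#' @param target,masker [mic_frame()] objects.
#' @param snr_db Nominal SNR in dB.
#' @param ref Reference microphone, `"lf"` or `"rf"`.
#' @param base_spl Presentation level ceiling in dB SPL (default 65).
#' @return List: rescaled `target` and `masker`, and `levels` with the two
#'   presentation levels in dB SPL.
#' @export
set_snr_levels <- function(target, masker, snr_db, ref = c("lf", "rf"),
                           base_spl = 65) {
  ref <- match.arg(ref)
  stopifnot(inherits(target, "mic_frame"), inherits(masker, "mic_frame"))
  t_level <- active_speech_level(target[[ref]])$active_db
  m_level <- rms_db(masker[[ref]])
  if (!is.finite(t_level) || !is.finite(m_level))
    stop("silent target or masker")
  if (snr_db >= 0) {
    t_spl <- base_spl
    m_spl <- base_spl - snr_db
  } else {
    m_spl <- base_spl
    t_spl <- base_spl + snr_db
  }
  t_gain <- db2lin(spl_to_dbfs(t_spl) - t_level)
  m_gain <- db2lin(spl_to_dbfs(m_spl) - m_level)
  list(target = mic_scale(target, t_gain),
       masker = mic_scale(masker, m_gain),
       levels = list(target_spl = t_spl, masker_spl = m_spl))
}

raised_cosine_ramps <- function(n, ramp_samples) {
  env <- rep(1, n)
  r <- seq_len(ramp_samples)
  up <- 0.5 * (1 - cos(pi * (r - 1) / (ramp_samples - 1)))
  env[r] <- up
  env[(n - ramp_samples + 1):n] <- rev(up)
  env
}

#' Assemble a test trial
#'
#' Places the target inside a masker that starts 900 ms before target onset
#' and ends 900 ms after target offset, with 100-ms raised-cosine ramps on
#' the masker.  The per-source clean components are retained so that oracle
#' SNR and mask computations remain possible; the mixture equals their
#' sample-exact sum.
#'
#' @param target,masker [mic_frame()] objects at matched levels (see
#'   [set_snr_levels()]); the masker must be at least 1.8 s longer than the
#'   target.
#' @param snr_db Nominal SNR recorded in the stimulus metadata.
#' @param lead_s Masker lead/lag around the target (default 0.9 s).
#' @param ramp_s Raised-cosine ramp duration (default 0.1 s).
#' @return Object of class `trial_stimulus`: `mics` (mixture),
#'   `target_onset_s`, `target_offset_s`, `snr_db`, `clean_refs` (list with
#'   `target` and `masker` [mic_frame()] components).
#' @export
assemble_trial <- function(target, masker, snr_db, lead_s = 0.9,
                           ramp_s = 0.1) {
  stopifnot(inherits(target, "mic_frame"), inherits(masker, "mic_frame"))
  fs <- target$lf$fs
  nt <- length(target$lf$samples)
  lead <- as.integer(round(lead_s * fs))
  total <- nt + 2L * lead
  if (length(masker$lf$samples) < total)
    stop("masker too short: needs >= target duration + ", 2 * lead_s, " s")
  ramp <- as.integer(round(ramp_s * fs))
  env <- raised_cosine_ramps(total, ramp)
  masker_cut <- mic_apply(masker, function(w)
    wave_mono(w$samples[seq_len(total)] * env, w$fs))
  target_pad <- mic_apply(target, function(w)
    wave_mono(c(rep(0, lead), w$samples, rep(0, lead)), w$fs))
  mix <- mic_add(target_pad, masker_cut)
  structure(list(mics = mix,
                 target_onset_s = lead / fs,
                 target_offset_s = (lead + nt) / fs,
                 snr_db = snr_db,
                 clean_refs = list(target = target_pad, masker = masker_cut)),
            class = "trial_stimulus")
}

#' Synthesise a sentence-like utterance
#'
#' Harmonic excitation with a slowly drifting fundamental (100-220 Hz),
#' shaped by per-word formant resonances, with word-like amplitude gaps.
#' A stand-in for recorded sentence material; every utterance carries five
#' scoring keywords as metadata.
#'
#' @param duration_s Utterance duration in seconds (1 to 3).
#' @param seed Integer seed.
#' @return List: `wave` ([wave_mono()], fs 16 kHz), `keyword_count = 5`,
#'   `f0_mean` (Hz).
#' @export
synth_utterance <- function(duration_s = 2, seed = 1) {
  stopifnot(duration_s >= 1, duration_s <= 3)
  fs <- 16000
  set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  f0_base <- stats::runif(1, 110, 190)
  drift <- cumsum(stats::rnorm(ceiling(duration_s * 10) + 2, 0, 2))
  f0 <- f0_base * 2 ^ (stats::approx(seq_along(drift), drift,
                                     xout = 1 + (seq_len(n) - 1) / fs * 10,
                                     rule = 2)$y / 60)
  f0 <- pmin(220, pmax(100, f0))
  phase <- 2 * pi * cumsum(f0) / fs
  n_harm <- floor(4000 / max(f0))
  src <- numeric(n)
  for (k in seq_len(n_harm)) src <- src + sin(k * phase) / k
  # word segmentation with 30-80 ms gaps
  n_words <- sample(4:7, 1)
  gaps <- stats::runif(n_words - 1, 0.03, 0.08)
  word_total <- duration_s - sum(gaps) - 0.1
  wlen <- stats::runif(n_words, 0.8, 1.2)
  wlen <- wlen / sum(wlen) * word_total
  out <- numeric(n)
  pos <- 0.05
  resonate <- function(x, fc, bw) {
    r <- exp(-pi * bw / fs)
    th <- 2 * pi * fc / fs
    a <- c(1, -2 * r * cos(th), r ^ 2)
    as.numeric(signal::filter(signal::Arma(b = (1 - r), a = a), x))
  }
  for (wdi in seq_len(n_words)) {
    i0 <- as.integer(round(pos * fs)) + 1L
    i1 <- min(n, as.integer(round((pos + wlen[wdi]) * fs)))
    seg <- src[i0:i1]
    formants <- c(stats::runif(1, 300, 800), stats::runif(1, 900, 2000),
                  stats::runif(1, 2200, 3200))
    for (fc in formants) seg <- resonate(seg, fc, 140)
    m <- length(seg)
    edge <- min(m %/% 2, as.integer(0.03 * fs))
    env <- raised_cosine_ramps(m, max(2, edge))
    out[i0:i1] <- out[i0:i1] + seg * env
    pos <- pos + wlen[wdi] + if (wdi < n_words) gaps[wdi] else 0
  }
  out <- out / sqrt(mean(out ^ 2)) * 0.05
  list(wave = wave_mono(out, fs), keyword_count = 5L,
       f0_mean = mean(f0))
}

#' Render a diffuse noise field
#'
#' Sums independent speech-shaped noise streams rendered from azimuths evenly
#' spaced around the head (anechoic paths plus the scene's reverberant tail
#' when `t60 > 0`), producing a spatially diffuse masker.
#'
#' @param ref_speech Spectrum reference [wave_mono()].
#' @param duration_s Duration in seconds.
#' @param geom [bte_array_geometry()].
#' @param scene [scene_spec()]; its `t60`, `drr_db`, `source_distance` and
#'   `seed` are used.
#' @param n_dirs Number of incidence directions (default 8).
#' @return A [mic_frame()].
#' @export
render_diffuse_noise <- function(ref_speech, duration_s, geom, scene,
                                 n_dirs = 8) {
  az <- seq(0, 360 - 360 / n_dirs, by = 360 / n_dirs)
  acc <- NULL
  for (k in seq_len(n_dirs)) {
    nz <- make_noise("ssn", ref_speech, duration_s,
                     seed = scene$seed * 131L + k)
    irs <- simulate_brirs(geom, az[k], scene$source_distance,
                          t60 = scene$t60, drr_db = scene$drr_db,
                          fs = ref_speech$fs, seed = scene$seed * 17L + k)
    r <- render_scene(nz, irs)
    acc <- if (is.null(acc)) r else {
      n_min <- min(length(acc$lf$samples), length(r$lf$samples))
      trim <- function(m) mic_apply(m, function(w)
        wave_mono(w$samples[seq_len(n_min)], w$fs))
      mic_add(trim(acc), trim(r))
    }
  }
  acc
}
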