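# Forward-model EEG session simulator with ground truth.
#
# Sources (all mixed instantaneously and linearly, in microvolts):
#   * one SSVEP source per trial: sinusoid at the trial's flicker frequency
#     plus its 2nd harmonic, random phase per trial, occipital/parietal
#     topography, active only during the stimulus phase;
#   * frontal eye blinks: raised-cosine pulses at homogeneous-Poisson times;
#   * background: independent 1/f ("pink") sources mixed through a random
#     spatial matrix (volume conduction) plus small white sensor noise;
#   * 50 Hz line interference with a broad topography.

default_ssvep_topography <- function(labels = default_montage()) {
  w <- c(FP1 = 0.05, FP2 = 0.05, F3 = 0.10, F4 = 0.10, C3 = 0.20, C4 = 0.20,
         P3 = 0.60, P4 = 0.60, F7 = 0.05, F8 = 0.05, T3 = 0.05, T4 = 0.05,
         T5 = 0.35, T6 = 0.35, O1 = 1.00, O2 = 1.00)
  out <- w[toupper(labels)]
  out[is.na(out)] <- 0.05
  names(out) <- toupper(labels)
  out
}

default_blink_topography <- function(labels = default_montage()) {
  w <- c(FP1 = 1.00, FP2 = 1.00, F3 = 0.45, F4 = 0.45, C3 = 0.10, C4 = 0.10,
         P3 = 0.03, P4 = 0.03, F7 = 0.70, F8 = 0.70, T3 = 0.10, T4 = 0.10,
         T5 = 0.03, T6 = 0.03, O1 = 0.02, O2 = 0.02)
  out <- w[toupper(labels)]
  out[is.na(out)] <- 0.03
  names(out) <- toupper(labels)
  out
}

#' Simulation configuration
#'
#' Parameters of the synthetic EEG session generator. Defaults emulate a
#' 16-channel, 250 Hz recording of a four-command SSVEP session: 4 uV
#' fundamental + 2 uV second-harmonic SSVEP with occipital-dominant
#' topography, spatially mixed 1/f background of about 10 uV RMS per
#' channel, 2 uV of 50 Hz line interference, and 80 uV frontal blinks at
#' 10 per minute.
#'
#' @param srate Sampling rate in Hz (default 250). Must exceed twice the
#'   highest modeled frequency (2nd harmonic of the fastest stimulus and the
#'   line frequency).
#' @param labels Channel labels (default [default_montage()]).
#' @param ssvep_amplitude Numeric vector of per-harmonic amplitudes in uV at
#'   the topography's unit-weight channel; element h is the amplitude of
#'   harmonic h (default `c(4, 2)`).
#' @param ssvep_topography,blink_topography Named per-channel weight vectors
#'   scaled so that their maximum is 1.
#' @param noise_exponent Spectral exponent of the 1/f background (default 1).
#' @param noise_scale Per-channel RMS of the mixed background in uV
#'   (default 10); 0 disables background noise.
#' @param line_amplitude Amplitude of 50 Hz line interference in uV
#'   (default 2).
#' @param line_freq Line frequency in Hz (default 50).
#' @param blink_rate Blink events per minute (homogeneous Poisson;
#'   default 10).
#' @param blink_amplitude Blink peak amplitude in uV at the unit-weight
#'   channel (default 80).
#' @param blink_duration_s Blink pulse duration in seconds (default 0.3).
#' @param amplitude_jitter Half-width of the multiplicative uniform
#'   trial-to-trial SSVEP amplitude jitter (default 0.2, i.e. x0.8..x1.2).
#' @param sensor_noise Standard deviation of additive white sensor noise in
#'   uV (default 0.5).
#' @param seed Integer seed for all randomness in [simulate_session()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(srate = 250, labels = default_montage(),
                       ssvep_amplitude = c(4, 2),
                       ssvep_topography = default_ssvep_topography(labels),
                       blink_topography = default_blink_topography(labels),
                       noise_exponent = 1, noise_scale = 10,
                       line_amplitude = 2, line_freq = 50,
                       blink_rate = 10, blink_amplitude = 80,
                       blink_duration_s = 0.3,
                       amplitude_jitter = 0.2, sensor_noise = 0.5,
                       seed = NULL) {
  check_scalar_pos(srate, "srate")
  labels <- toupper(labels)
  amp_args <- list(ssvep_amplitude = ssvep_amplitude,
                   noise_scale = noise_scale, line_amplitude = line_amplitude,
                   blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                   sensor_noise = sensor_noise)
  for (nm in names(amp_args)) {
    v <- amp_args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stopf("`%s` must be non-negative and finite", nm)
  }
  check_scalar_pos(blink_duration_s, "blink_duration_s")
  check_scalar_pos(noise_exponent, "noise_exponent")
  for (nm in c("ssvep_topography", "blink_topography")) {
    topo <- get(nm)
    if (length(topo) != length(labels))
      stopf("`%s` must have one weight per channel", nm)
    if (any(topo < 0) || max(topo) <= 0)
      stopf("`%s` weights must be non-negative with a positive maximum", nm)
  }
  ssvep_topography <- ssvep_topography / max(ssvep_topography)
  blink_topography <- blink_topography / max(blink_topography)
  structure(
    list(srate = srate, labels = labels, ssvep_amplitude = ssvep_amplitude,
         ssvep_topography = unname(ssvep_topography),
         blink_topography = unname(blink_topography),
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         line_amplitude = line_amplitude, line_freq = line_freq,
         blink_rate = blink_rate, blink_amplitude = blink_amplitude,
         blink_duration_s = blink_duration_s,
         amplitude_jitter = amplitude_jitter, sensor_noise = sensor_noise,
         seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d ch @ %g Hz | SSVEP %s uV | noise 1/f^%g x %g uV | ",
    "line %g uV @ %g Hz | blinks %g/min x %g uV\n"),
    length(x$labels), x$srate,
    paste(x$ssvep_amplitude, collapse = "+"), x$noise_exponent,
    x$noise_scale, x$line_amplitude, x$line_freq, x$blink_rate,
    x$blink_amplitude))
  invisible(x)
}

#' Eye-blink waveform template
#'
#' A smooth unimodal raised-cosine (squared-sine) pulse used as the blink
#' source waveform. Peak value equals `amplitude`; spectral energy is
#' concentrated below 4 Hz for typical durations (~0.3 s).
#'
#' @param duration_s Pulse duration in seconds (> 0).
#' @param amplitude Peak amplitude (>= 0).
#' @param srate Sampling rate in Hz.
#' @return Numeric waveform of `round(duration_s * srate)` samples.
#' @export
blink_template <- function(duration_s, amplitude, srate = 250) {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(srate, "srate")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stopf("`amplitude` must be a single non-negative number")
  n <- max(3L, round(duration_s * srate))
  # sin^2 bell peaking exactly at amplitude mid-pulse
  amplitude * sin(pi * (seq_len(n) - 0.5) / n)^2
}

#' 1/f ("pink") noise
#'
#' Spectral-synthesis generator: white Gaussian spectrum shaped by
#' `1/f^(exponent/2)` with a 1 Hz knee (the spectrum is flat below the knee,
#' matching the low-frequency flattening of aperiodic EEG spectra), then
#' inverse-transformed and rescaled to standard deviation `scale`.
#'
#' @param n Number of samples (>= 2).
#' @param exponent Spectral exponent of the power spectral density
#'   (PSD ~ 1/f^exponent above the knee; default 1).
#' @param scale Output standard deviation (default 1); 0 yields zeros.
#' @param srate Sampling rate in Hz, used to place the knee (default 250).
#' @param knee_hz Knee frequency below which the PSD is flat (default 1).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, scale = 1, srate = 250, knee_hz = 1,
                       seed = NULL) {
  if (!is_count(n) || n < 2) stopf("`n` must be an integer >= 2")
  if (scale == 0) return(numeric(n))
  if (!is.null(seed)) return(with_seed(seed, pink_noise(n, exponent, scale, srate, knee_hz)))
  freqs <- seq(0, srate / 2, length.out = floor(n / 2) + 1)
  shape <- 1 / pmax(freqs, knee_hz)^(exponent / 2)
  shape[1] <- 0  # no DC
  nfreq <- length(freqs)
  re <- stats::rnorm(nfreq) * shape
  im <- stats::rnorm(nfreq) * shape
  spec <- complex(real = re, imaginary = im)
  spec[1] <- 0
  if (n %% 2 == 0) spec[nfreq] <- complex(real = re[nfreq], imaginary = 0)
  full <- c(spec, Conj(rev(spec[2:(nfreq - (n %% 2 == 0))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (scale / stats::sd(x))
}

#' Simulate a full EEG session
#'
#' Generates a continuous multichannel recording spanning every trial of
#' `schedule` under the forward model described in [sim_config()]. During
#' each trial's stimulus phase an SSVEP source (fundamental + harmonics at
#' the trial's flicker frequency, per-trial random phase and amplitude
#' jitter) is mixed through the SSVEP topography. Background 1/f noise,
#' 50 Hz line interference and Poisson-timed frontal blinks are always
#' present. Event markers are placed at every phase onset
#' (`sample = round(onset_s * srate)`). Bit-reproducible for a fixed
#' `config$seed`.
#'
#' @param schedule A [session_schedule()].
#' @param config A [sim_config()].
#' @param keep_sources If `TRUE`, attach ground truth as attribute
#'   `"sources"`: a list with the blink source time series, per-source
#'   topographies, and per-trial SSVEP source series.
#' @return An [eeg_recording()] (microvolts).
#' @export
simulate_session <- function(schedule, config = sim_config(),
                             keep_sources = FALSE) {
  stopifnot(inherits(schedule, "session_schedule"), inherits(config, "sim_config"))
  if (nrow(schedule$trials) == 0) stopf("schedule has no trials")
  n_harm <- length(config$ssvep_amplitude)
  fmax <- max(max(schedule$trials$frequency_hz) * n_harm, config$line_freq)
  if (config$srate <= 2 * fmax)
    stopf("sampling rate %g Hz does not exceed twice the highest modeled frequency (%g Hz)",
          config$srate, fmax)
  srate <- config$srate
  C <- length(config$labels)
  dur <- schedule_duration(schedule) + 1  # 1 s tail margin
  S <- round(dur * srate)

  with_seed(config$seed, {
    X <- matrix(0, C, S)

    # --- background: C independent pink sources through a random mixing
    truth_noise_mix <- NULL
    if (config$noise_scale > 0) {
      pinks <- vapply(seq_len(C),
                      function(i) pink_noise(S, config$noise_exponent, 1, srate),
                      numeric(S))                       # S x C
      M <- matrix(stats::rnorm(C * C), C, C) / sqrt(C)  # volume conduction
      bg <- M %*% t(pinks)                              # C x S
      bg <- bg * (config$noise_scale / sqrt(mean(bg^2)))
      X <- X + bg
      truth_noise_mix <- M
    }

    # --- SSVEP sources, one per trial during its stimulus phase
    off <- cumsum(c(0, schedule$timing))
    stim_len <- round(schedule$timing[["stimulus"]] * srate)
    ssvep_src <- numeric(S)
    for (k in seq_len(nrow(schedule$trials))) {
      tr <- schedule$trials[k, ]
      s0 <- round((tr$onset_s + off[2]) * srate)  # 0-based stimulus onset
      idx <- s0 + seq_len(stim_len)               # 1-based into X
      tt <- (seq_len(stim_len) - 1) / srate
      jit <- 1 + config$amplitude_jitter * stats::runif(1, -1, 1)
      wave <- numeric(stim_len)
      for (h in seq_len(n_harm)) {
        phase <- stats::runif(1, 0, 2 * pi)
        wave <- wave + config$ssvep_amplitude[h] *
          sin(2 * pi * h * tr$frequency_hz * tt + phase)
      }
      ssvep_src[idx] <- wave * jit
    }
    X <- X + config$ssvep_topography %o% ssvep_src

    # --- blinks: homogeneous Poisson train of raised-cosine pulses
    blink_src <- numeric(S)
    if (config$blink_rate > 0 && config$blink_amplitude > 0) {
      n_blinks <- stats::rpois(1, config$blink_rate * dur / 60)
      tmpl <- blink_template(config$blink_duration_s, config$blink_amplitude, srate)
      if (n_blinks > 0) {
        onsets <- sort(stats::runif(n_blinks, 0, dur - config$blink_duration_s))
        for (b in onsets) {
          i0 <- round(b * srate)
          idx <- i0 + seq_along(tmpl)
          idx <- idx[idx <= S]
          blink_src[idx] <- blink_src[idx] + tmpl[seq_along(idx)]
        }
      }
      X <- X + config$blink_topography %o% blink_src
    }

    # --- line interference, broad topography
    line_topo <- rep(1, C)
    if (config$line_amplitude > 0) {
      tt <- (seq_len(S) - 1) / srate
      line_phase <- stats::runif(1, 0, 2 * pi)
      X <- X + line_topo %o%
        (config$line_amplitude * sin(2 * pi * config$line_freq * tt + line_phase))
    }

    if (config$sensor_noise > 0)
      X <- X + matrix(stats::rnorm(C * S, sd = config$sensor_noise), C, S)

    # --- event markers at every phase onset
    phases <- names(schedule$timing)
    ev <- do.call(rbind, lapply(seq_len(nrow(schedule$trials)), function(k) {
      tr <- schedule$trials[k, ]
      data.frame(
        sample_index = round((tr$onset_s + off[seq_along(phases)]) * srate),
        label = paste(phases, tr$direction, sep = "/"),
        trial = tr$trial, stringsAsFactors = FALSE
      )
    }))
    rec <- eeg_recording(X, srate, config$labels, ev)
    if (keep_sources) {
      attr(rec, "sources") <- list(
        ssvep = ssvep_src, blink = blink_src,
        ssvep_topography = config$ssvep_topography,
        blink_topography = config$blink_topography,
        noise_mixing = truth_noise_mix
      )
    }
    rec
  })
}
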