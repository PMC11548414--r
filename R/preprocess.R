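# Zero-phase filtering, band splitting, channel selection and epoching.

# Steady-state initial filter conditions for a unit-step input (the
# classical filtfilt zi construction): scaling by the first sample lets
# each pass start transient-free on locally constant data.
#' @keywords internal
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1
  b <- c(b, rep(0, n + 1 - length(b)))
  a <- c(a, rep(0, n + 1 - length(a)))
  A <- rbind(-a[2:(n + 1)], cbind(diag(n - 1), 0))
  B <- b[2:(n + 1)] - a[2:(n + 1)] * b[1]
  solve(diag(n) - t(A), B)
}

# Forward-backward application of an IIR filter (zero phase). Both ends are
# padded with an odd reflection tapered smoothly to the endpoint value, and
# each pass starts from steady-state initial conditions, so edge transients
# stay confined to a few filter time constants. Narrowband filters with
# long impulse responses (the high-Q notch) pass a longer `npad` covering
# their ringing time.
#' @keywords internal
filtfilt_reflect <- function(b, a, x, npad = 3L * max(length(a), length(b))) {
  n <- length(x)
  if (n <= npad + 1) npad <- max(0L, n - 2L)
  zi <- lfilter_zi(b, a)
  if (npad > 0) {
    w <- cos(pi * seq_len(npad) / (2 * npad))^2      # 1 -> 0 fade
    head_pad <- x[1] + (x[1] - x[1 + seq_len(npad)]) * w
    tail_pad <- x[n] + (x[n] - x[n - seq_len(npad)]) * w
    xp <- c(rev(head_pad), x, tail_pad)
  } else xp <- x
  y <- signal::filter(b, a, xp, init = zi * xp[1])
  y <- rev(as.numeric(y))
  y <- signal::filter(b, a, y, init = zi * y[1])
  y <- rev(as.numeric(y))
  if (npad > 0) y <- y[(npad + 1):(npad + n)]
  y
}

apply_filter_rec <- function(rec, b, a, npad = 3L * max(length(a), length(b))) {
  out <- t(apply(rec$data, 1, function(ch) filtfilt_reflect(b, a, ch, npad)))
  set_data(rec, out)
}

# 2nd-order IIR notch (biquad), quality factor Q
#' @keywords internal
design_notch <- function(freq, srate, q = 30) {
  w0 <- 2 * pi * freq / srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Zero-phase notch filter
#'
#' Removes narrowband line interference with a 2nd-order IIR notch
#' (quality factor `q`, default 30) applied forward and backward
#' (zero phase). Attenuation at `freq` exceeds 30 dB while the passband
#' outside +/-2 Hz of the notch is essentially untouched.
#'
#' @param rec An [eeg_recording()].
#' @param freq Notch frequency in Hz; must be below the Nyquist frequency.
#' @param q Quality factor (center frequency / -3 dB bandwidth).
#' @return The filtered [eeg_recording()] (same shape and events).
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar_pos(freq, "freq")
  if (freq >= rec$srate / 2)
    stopf("notch frequency %g Hz is not below Nyquist (%g Hz)", freq, rec$srate / 2)
  d <- design_notch(freq, rec$srate, q)
  # ring-down time constant of a Q-notch is ~2Q/omega0; pad three of them
  npad <- ceiling(3 * q * rec$srate / (pi * freq))
  apply_filter_rec(rec, d$b, d$a, npad)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward with
#' odd-reflection padding (zero phase, no group delay).
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < Nyquist`.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar_pos(low, "low")
  check_scalar_pos(high, "high")
  nyq <- rec$srate / 2
  if (!(low < high && high < nyq))
    stopf("invalid band [%g, %g] Hz: need 0 < low < high < Nyquist (%g Hz)",
          low, high, nyq)
  bt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  apply_filter_rec(rec, bt$b, bt$a)
}

#' Canonical analysis band definitions
#'
#' Alpha 8-12 Hz, beta1 12-20 Hz, beta2 20-30 Hz, gamma 30-50 Hz.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
band_definitions <- function() {
  data.frame(name = c("alpha", "beta1", "beta2", "gamma"),
             low = c(8, 12, 20, 30), high = c(12, 20, 30, 50),
             stringsAsFactors = FALSE)
}

#' Split a recording into frequency bands
#'
#' Applies [bandpass_filter()] once per band definition.
#'
#' @param rec An [eeg_recording()].
#' @param bands Data frame with columns `name`, `low`, `high`
#'   (default [band_definitions()]).
#' @return Named list of filtered recordings, one per band; an empty list
#'   for zero bands.
#' @export
split_bands <- function(rec, bands = band_definitions()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.data.frame(bands) || !all(c("name", "low", "high") %in% names(bands)))
    stopf("`bands` must be a data.frame with columns name, low, high")
  if (nrow(bands) == 0) return(structure(list(), names = character()))
  if (any(!(bands$low > 0 & bands$low < bands$high)))
    stopf("every band needs 0 < low < high")
  out <- lapply(seq_len(nrow(bands)),
                function(i) bandpass_filter(rec, bands$low[i], bands$high[i]))
  names(out) <- bands$name
  out
}

#' Select and reorder channels
#'
#' @param rec An [eeg_recording()].
#' @param labels Channel labels to keep, in the desired output order
#'   (case-insensitive); default the eight analysis channels.
#' @return An [eeg_recording()] with the requested rows in the requested
#'   order; events preserved.
#' @export
select_channels <- function(rec, labels = analysis_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  labels <- toupper(labels)
  missing <- setdiff(labels, rec$labels)
  if (length(missing))
    stopf("unknown channel label(s): %s (recording has: %s)",
          paste(missing, collapse = ", "), paste(rec$labels, collapse = ", "))
  idx <- match(labels, rec$labels)
  eeg_recording(rec$data[idx, , drop = FALSE], rec$srate, labels, rec$events)
}

#' Cut a recording into trial epochs
#'
#' Extracts one fixed-length epoch per trial, time-locked to the trial's
#' prompt-onset marker and spanning the full trial
#' (`sum(timing)` seconds, half-open sample window, 0-based offsets).
#' Phase boundaries are recorded at the cumulative phase durations.
#'
#' @param rec An [eeg_recording()] whose events contain `prompt/<direction>`
#'   markers.
#' @param timing Named phase durations in seconds (default [default_timing()]).
#' @return List of `trial_epoch` objects, each a list with `data`
#'   (channels x samples), `direction`, `frequency`, `trial`,
#'   `phase_bounds` (named 0-based sample offsets of prompt/stimulus/action/
#'   rest starts plus `end`).
#' @export
epoch_by_events <- function(rec, timing = default_timing()) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  prompts <- ev[grepl("^prompt/", ev$label), , drop = FALSE]
  if (nrow(prompts) == 0) stopf("recording has no prompt/* event markers")
  epoch_len <- round(sum(timing) * rec$srate)
  bounds <- round(cumsum(c(0, timing)) * rec$srate)
  names(bounds) <- c(names(timing), "end")
  fmap <- direction_frequencies()
  bad <- prompts$trial[prompts$sample_index + epoch_len > n_samples(rec)]
  if (length(bad))
    stopf("recording ends before trial(s) %s complete", paste(bad, collapse = ", "))
  lapply(seq_len(nrow(prompts)), function(k) {
    s0 <- prompts$sample_index[k]
    direction <- sub("^prompt/", "", prompts$label[k])
    structure(
      list(data = rec$data[, s0 + seq_len(epoch_len), drop = FALSE],
           direction = direction,
           frequency = unname(fmap[direction]),
           trial = prompts$trial[k],
           srate = rec$srate,
           phase_bounds = bounds),
      class = "trial_epoch"
    )
  })
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat(sprintf("<trial_epoch> trial %d: %s (%g Hz), %d ch x %d samples\n",
              x$trial, x$direction, x$frequency, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Extract one phase of a trial epoch
#'
#' @param epoch A `trial_epoch` from [epoch_by_events()].
#' @param phase One of `"prompt"`, `"stimulus"`, `"action"`, `"rest"`.
#' @return Channels x samples matrix of that phase's half-open sample window.
#' @export
phase_slice <- function(epoch, phase = "stimulus") {
  stopifnot(inherits(epoch, "trial_epoch"))
  b <- epoch$phase_bounds
  if (!phase %in% setdiff(names(b), "end"))
    stopf("unknown phase '%s'", phase)
  i <- match(phase, names(b))
  epoch$data[, (b[i] + 1):b[i + 1], drop = FALSE]
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 50% overlap.
#'
#' @param x Numeric signal.
#' @param srate Sampling rate in Hz.
#' @param nperseg Samples per segment (default `min(length(x), 1024)`).
#' @return List with `freq` (Hz) and `power` (density, arbitrary units).
#' @export
welch_psd <- function(x, srate, nperseg = min(length(x), 1024L)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1) / (nperseg - 1))
  u <- sum(win^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  power <- acc / (length(starts) * u * srate)
  # one-sided: double interior bins
  if (nf > 2) power[2:(nf - 1)] <- 2 * power[2:(nf - 1)]
  list(freq = seq(0, srate / 2, length.out = nf), power = power)
}
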