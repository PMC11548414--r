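tone_recording <- function(freq, srate = 250, dur = 10, chans = 2) {
  t <- seq(0, dur - 1 / srate, by = 1 / srate)
  x <- sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, chans), nrow = chans, byrow = TRUE),
                srate, paste0("C", seq_len(chans)))
}

rms <- function(x) sqrt(mean(x^2))

test_that("the notch removes its target frequency and spares neighbours", {
  # attenuation is a transfer-function property: measure it in steady
  # state, past the tone-onset transient at the record edges
  r50 <- tone_recording(50)
  out <- notch_filter(r50, 50)
  mid <- 500:2000
  expect_lte(rms(out$data[1, mid]) / rms(r50$data[1, mid]), 0.032)  # >= 30 dB

  r10 <- tone_recording(10)
  out10 <- notch_filter(r10, 50)
  mid <- 500:2000
  expect_equal(rms(out10$data[1, mid]) / rms(r10$data[1, mid]), 1,
               tolerance = 0.01)

  zero <- eeg_recording(matrix(0, 2, 1000), 250, c("A", "B"))
  expect_identical(notch_filter(zero, 50)$data, zero$data)
  expect_error(notch_filter(r10, 130), "Nyquist")
})

test_that("the 8-50 Hz band-pass attenuates out-of-band tones and passes in-band ones", {
  r4 <- tone_recording(4)
  expect_lte(rms(bandpass_filter(r4, 8, 50)$data[1, ]) / rms(r4$data[1, ]), 0.1)
  r20 <- tone_recording(20)
  mid <- 500:2000
  out <- bandpass_filter(r20, 8, 50)
  expect_equal(rms(out$data[1, mid]) / rms(r20$data[1, mid]), 1,
               tolerance = 0.05)
  expect_error(bandpass_filter(r20, 50, 8), "invalid band")
  expect_error(bandpass_filter(r20, 8, 200), "invalid band")
})

test_that("filtering is zero-phase and passband-idempotent", {
  # symmetric in-band burst stays symmetric (no group delay)
  i <- seq_len(2001) - 1001
  x <- exp(-(i / 50)^2) * cos(2 * pi * 10 * i / 250)
  rec <- eeg_recording(matrix(x, 1), 250, "CZ")
  out <- bandpass_filter(rec, 1, 40)$data[1, ]
  expect_lte(abs(which.max(out) - 1001), 1)
  expect_gt(max(out), 0.5)   # the burst actually passes

  r20 <- tone_recording(20)
  once <- bandpass_filter(r20, 8, 50)
  twice <- bandpass_filter(once, 8, 50)
  mid <- 500:2000
  expect_lt(abs(rms(twice$data[1, mid]) / rms(once$data[1, mid]) - 1), 0.02)
})

test_that("band splitting returns one shaped recording per canonical band", {
  rec <- tone_recording(10, chans = 3)
  bands <- split_bands(rec)
  expect_named(bands, c("alpha", "beta1", "beta2", "gamma"))
  for (b in bands) expect_identical(dim(b$data), dim(rec$data))
  # a 10 Hz tone lives in alpha, not beta2
  mid <- 500:2000
  expect_lte(rms(bands$beta2$data[1, mid]) / rms(bands$alpha$data[1, mid]), 0.05)
  expect_length(split_bands(rec, band_definitions()[0, ]), 0)
})

test_that("channel selection reorders rows, preserves events, and names bad labels", {
  rec <- small_session()
  sel <- select_channels(rec, analysis_channels())
  expect_identical(sel$labels, analysis_channels())
  expect_identical(sel$data[1, ], rec$data[match("F3", rec$labels), ])
  expect_identical(sel$events, rec$events)
  ident <- select_channels(rec, rec$labels)
  expect_identical(ident$data, rec$data)
  expect_error(select_channels(rec, c("O1", "XX")), "XX")
})

test_that("epoching yields 3000-sample trials with canonical phase boundaries", {
  rec <- small_session()
  ep <- epoch_by_events(rec)
  expect_length(ep, 8)
  expect_true(all(vapply(ep, function(e) ncol(e$data), numeric(1)) == 3000))
  b <- ep[[1]]$phase_bounds
  expect_equal(unname(b), c(0, 250, 1500, 2500, 3000))
  # stimulus slice spans samples [250, 1500)
  sl <- phase_slice(ep[[1]], "stimulus")
  expect_equal(ncol(sl), 1250)
  expect_identical(sl[, 1], ep[[1]]$data[, 251])
})

test_that("a recording ending mid-trial names the truncated trial", {
  rec <- small_session()
  short <- eeg_recording(rec$data[, 1:20000], rec$srate, rec$labels,
                         rec$events[rec$events$sample_index < 20000, ])
  expect_error(epoch_by_events(short), "trial")
})
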