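test_that("a noise-free single-source trial has its spectral peak at the stimulus frequency", {
  sch <- session_schedule(4, 1, seed = 2)
  cfg <- sim_config(noise_scale = 0, line_amplitude = 0, blink_rate = 0,
                    sensor_noise = 0, amplitude_jitter = 0,
                    ssvep_amplitude = c(4, 0), seed = 1)
  rec <- simulate_session(sch, cfg)
  ep <- epoch_by_events(rec)
  bw <- ep[[which(vapply(ep, `[[`, character(1), "direction") == "backward")]]
  o1 <- phase_slice(bw, "stimulus")[match("O1", rec$labels), ]
  psd <- welch_psd(o1, rec$srate, nperseg = 1250)
  expect_equal(psd$freq[which.max(psd$power)], 12, tolerance = 0.21)
})

test_that("simulation is bit-reproducible for a fixed seed and varies across seeds", {
  sch <- session_schedule(4, 1, seed = 3)
  r1 <- simulate_session(sch, sim_config(seed = 10))
  r2 <- simulate_session(sch, sim_config(seed = 10))
  r3 <- simulate_session(sch, sim_config(seed = 11))
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  expect_false(identical(r1$data, r3$data))
})

test_that("event markers sit at round(onset_s * srate) for every phase", {
  sch <- session_schedule(8, 2, seed = 4)
  rec <- simulate_session(sch, sim_config(seed = 5))
  off <- cumsum(c(0, sch$timing))[1:4]
  expected <- unlist(lapply(sch$trials$onset_s,
                            function(o) round((o + off) * 250)))
  expect_equal(rec$events$sample_index, as.integer(expected))
  expect_true(all(rec$events$label %in% event_vocabulary()))
})

test_that("blink template is a unimodal low-frequency pulse with exact peak", {
  expect_equal(blink_template(0.3, 0, 250), rep(0, 75))
  w <- blink_template(0.3, 80, 250)
  expect_equal(max(w), 80, tolerance = 1e-9)
  expect_true(all(diff(w[1:which.max(w)]) >= 0))       # unimodal rise
  # spectral centroid below 4 Hz
  sp <- Mod(fft(c(w, rep(0, 1024 - length(w)))))^2
  f <- seq(0, 250, length.out = 1025)[1:512]
  centroid <- sum(f * sp[1:512]) / sum(sp[1:512])
  expect_lt(centroid, 4)
})

test_that("pink noise has the requested spectral slope, scale and determinism", {
  for (ex in c(0.8, 1, 1.5)) {
    x <- pink_noise(2^16, exponent = ex, scale = 1, srate = 250, seed = 42)
    psd <- welch_psd(x, 250, nperseg = 4096)
    sel <- psd$freq >= 2 & psd$freq <= 100
    fit <- lm(log(psd$power[sel]) ~ log(psd$freq[sel]))
    expect_equal(unname(coef(fit)[2]), -ex, tolerance = 0.3)
  }
  expect_identical(pink_noise(1000, seed = 7), pink_noise(1000, seed = 7))
  expect_identical(pink_noise(512, scale = 0), rep(0, 512))
  expect_equal(sd(pink_noise(4096, scale = 2.5, seed = 1)), 2.5, tolerance = 1e-9)
})

test_that("frequencies above Nyquist are rejected", {
  sch <- session_schedule(4, 1, seed = 1)
  expect_error(simulate_session(sch, sim_config(srate = 60)), "Nyquist|twice")
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(noise_scale = -1), "noise_scale")
  expect_error(sim_config(ssvep_amplitude = c(-4, 2)), "ssvep_amplitude")
  expect_error(sim_config(ssvep_topography = rep(0, 16)), "topography")
})

test_that("stronger SSVEP sources never hurt downstream accuracy", {
  accs <- vapply(c(1, 3, 6), function(amp) {
    sch <- session_schedule(16, 1, seed = 21)
    cfg <- sim_config(ssvep_amplitude = amp * c(1, 0.5), seed = 22)
    rec <- simulate_session(sch, cfg)
    fit <- quiet(ssvep_decode(rec, methods = "svm", use_ica = FALSE,
                              seed = 23))
    fit$evals$svm$average_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.5)
})

test_that("the default simulator supports accurate decoding at modest session length", {
  sch <- session_schedule(40, 1, seed = 31)
  rec <- simulate_session(sch, sim_config(seed = 32))
  fit <- quiet(ssvep_decode(rec, methods = "svm", eval_level = "trial",
                            seed = 33))
  expect_gte(fit$evals$svm$average_accuracy, 0.9)
})
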