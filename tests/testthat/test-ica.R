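test_that("center_whiten yields identity covariance and detects rank deficiency", {
  set.seed(1)
  X <- matrix(rnorm(5 * 4000), 5) * (1:5) + 3
  cw <- center_whiten(X)
  expect_equal(cw$Z %*% t(cw$Z) / (ncol(X) - 1), diag(5), tolerance = 1e-8)
  expect_equal(cw$K %*% (X - cw$mean), cw$Z)

  # already-white input: whitening transform is (close to) orthogonal
  Zw <- cw$Z
  cw2 <- center_whiten(Zw)
  expect_equal(cw2$K %*% t(cw2$K), diag(5), tolerance = 1e-2)

  Xc <- X; Xc[3, ] <- 2
  expect_error(center_whiten(Xc), "rank")
  expect_error(center_whiten(X[, 1:4]), "more samples")
})

test_that("FastICA recovers independent sources up to sign and permutation", {
  set.seed(2)
  n <- 5000
  S <- rbind(runif(n, -1, 1), sign(runif(n, -1, 1)) * rexp(n))
  A <- matrix(c(1, 0.6, -0.4, 1.2), 2)
  m <- fastica(A %*% S, seed = 4)
  rec <- ica_sources(m, A %*% S)
  cors <- abs(cor(t(rec), t(S)))
  # best match per true source
  expect_true(all(apply(cors, 2, max) >= 0.95))
  expect_true(m$converged)
})

test_that("on independent white input the demixing is a signed permutation", {
  set.seed(3)
  X <- rbind(runif(8000, -1, 1), sign(runif(8000, -1, 1)) * rexp(8000),
             runif(8000, -1, 1)^3)
  m <- fastica(X, seed = 5)
  P <- m$demixing %*% diag(apply(X, 1, sd))
  expect_lt(amari_index(P), 0.1)
})

test_that("component counts and model invariants hold", {
  set.seed(4)
  X <- matrix(rnorm(4 * 3000), 4) * c(1, 2, 3, 4)
  expect_error(fastica(X, n_components = 5), "n_components")
  m <- quiet(fastica(X, n_components = 3, seed = 1))
  expect_equal(dim(m$demixing), c(3L, 4L))
  # sources have unit variance on training data
  expect_equal(unname(apply(ica_sources(m, X), 1, var)), rep(1, 3),
               tolerance = 1e-6)
  # mixing is the pseudo-inverse of the demixing
  expect_equal(m$demixing %*% m$mixing, diag(3), tolerance = 1e-6)
})

test_that("back-projection reproduces the input when nothing is removed", {
  rec <- small_session()
  p <- notch_filter(rec, 50)
  m <- quiet(fastica(p$data[, 1:20000], seed = 6))
  X <- p$data[, 1:20000]
  expect_lt(max(abs(remove_components(X, m, integer()) - X)), 1e-6)
  # removing everything leaves only the channel means
  allgone <- remove_components(X, m, seq_len(nrow(m$demixing)))
  expect_equal(allgone, matrix(m$mean, nrow(X), ncol(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(remove_components(X, m, 99), "out of range")
})

test_that("the blink component is flagged and its removal cleans frontal low frequencies", {
  # blink-rich session: strong frequent blinks (upper physiological range)
  # so frontal low-frequency power is artifact-dominated and the size of
  # the removal effect is measurable against the 1/f background
  sch <- session_schedule(8, 1, seed = 11)
  rec <- simulate_session(sch,
                          sim_config(blink_amplitude = 200, blink_rate = 18,
                                     seed = 12),
                          keep_sources = TRUE)
  truth <- attr(rec, "sources")
  p <- notch_filter(rec, 50)
  m <- quiet(fastica(p$data, seed = 7))
  fl <- flag_artifact_components(m, p)
  src <- ica_sources(m, p$data)
  cors <- abs(cor(t(src), truth$blink))
  blink_ic <- which.max(cors)
  expect_gt(max(cors), 0.9)
  expect_identical(fl$flagged, blink_ic)
  expect_true(all(fl$scores$score >= 0 & fl$scores$score <= 1))

  cleaned <- remove_components(p$data, m, fl$flagged)
  lowpow <- function(x) {
    psd <- welch_psd(x, 250, 2048)
    sum(psd$power[psd$freq < 4])
  }
  fp1 <- match("FP1", p$labels)
  expect_gte(1 - lowpow(cleaned[fp1, ]) / lowpow(p$data[fp1, ]), 0.8)
  # occipital SSVEP power untouched: compare at a stimulus frequency
  o1 <- match("O1", p$labels)
  bandpow <- function(x, f) {
    psd <- welch_psd(x, 250, 4096)
    sum(psd$power[abs(psd$freq - f) < 0.5])
  }
  ratio <- bandpow(cleaned[o1, ], 10) / bandpow(p$data[o1, ], 10)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("flagging respects thresholds and degenerate sessions", {
  rec <- small_session()
  p <- notch_filter(rec, 50)
  m <- quiet(fastica(p$data[, 1:20000], seed = 8))
  sub <- eeg_recording(p$data[, 1:20000], p$srate, p$labels)
  expect_length(flag_artifact_components(m, sub, threshold = 1.0)$flagged, 0)
  expect_error(flag_artifact_components(m, sub, frontal_labels = "FPZ"), "FPZ")

  # no blinks simulated -> nothing to flag
  sch <- session_schedule(4, 1, seed = 9)
  noblink <- simulate_session(sch, sim_config(blink_rate = 0, seed = 10))
  pn <- notch_filter(noblink, 50)
  mn <- quiet(fastica(pn$data, seed = 11))
  expect_length(flag_artifact_components(mn, pn)$flagged, 0)
})

test_that("mean Amari index over repeated seeded mixtures is small", {
  idx <- vapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 10000
    S <- rbind(runif(n, -1, 1),
               sign(runif(n, -1, 1)) * rexp(n),
               sin(2 * pi * 7 * seq_len(n) / 250))
    A <- matrix(rnorm(9), 3)
    m <- fastica(A %*% S, seed = s)
    amari_index(m$demixing %*% A)
  }, numeric(1))
  expect_lt(mean(idx), 0.1)
})

test_that("ICA models serialize and reload without loss", {
  set.seed(12)
  X <- rbind(runif(3000, -1, 1), sign(runif(3000, -1, 1)) * rexp(3000))
  m <- fastica(X, seed = 13)
  path <- tempfile(fileext = ".json")
  write_ica_model(m, path)
  back <- read_ica_model(path)
  expect_equal(back$demixing, m$demixing, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$mixing, m$mixing, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ica_sources(back, X), ica_sources(m, X), tolerance = 1e-10)
})
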