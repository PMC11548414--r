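test_that("flicker sequences follow the sinusoidal closed form", {
  s <- flicker_sequence(10, 60, 13, depth = "high")
  expect_equal(s$values[1], 1.0)                 # sin(pi/2) at frame 0
  # period fr/f = 6 frames at 10 Hz on a 60 Hz display
  expect_equal(s$values[1:6], s$values[7:12], tolerance = 1e-12)
  i <- 0:12
  expect_equal(s$values, 0.5 * sin(2 * pi * 10 * i / 60 + pi / 2) + 0.5)

  lo <- flicker_sequence(10, 60, 13, depth = "low")
  expect_equal(lo$values[1], 0.613)              # 0.149 + 0.464
  expect_equal(lo$values, 0.149 * sin(2 * pi * 10 * i / 60 + pi / 2) + 0.464)
})

test_that("sequence extrema match the modulation depth", {
  hi <- flicker_sequence(7.3, 60, 600, depth = "high")
  lo <- flicker_sequence(7.5, 60, 600, depth = "low")
  expect_true(all(hi$values >= 0 & hi$values <= 1))
  expect_equal(range(lo$values), c(0.315, 0.613), tolerance = 1e-12)
  expect_equal(range(hi$values), c(0, 1), tolerance = 1e-12)
})

test_that("invalid flicker arguments are rejected", {
  expect_error(flicker_sequence(-1, 60, 10), "freq")
  expect_error(flicker_sequence(10, 0, 10), "refresh")
  expect_error(flicker_sequence(10, 60, 0), "n_frames")
})

test_that("session schedules are balanced, blocked and seeded", {
  sch <- session_schedule(100, 2, seed = 5)
  expect_equal(nrow(sch$trials), 100)
  expect_equal(as.vector(table(sch$trials$block)), c(50, 50))
  expect_true(all(table(sch$trials$direction) == 25))
  expect_equal(unname(direction_frequencies()[sch$trials$direction]),
               sch$trials$frequency_hz)

  tiny <- session_schedule(4, 1, seed = 1)
  expect_setequal(tiny$trials$direction,
                  c("forward", "backward", "left", "right"))

  # balance holds for any 4k
  for (k in c(2, 5, 7)) {
    s <- session_schedule(4 * k, 1, seed = k)
    expect_true(all(table(s$trials$direction) == k))
  }
})

test_that("schedule order is deterministic per seed and varies across seeds", {
  a <- session_schedule(40, 2, seed = 99)
  b <- session_schedule(40, 2, seed = 99)
  expect_identical(a$trials, b$trials)
  others <- vapply(1:20, function(s)
    identical(session_schedule(40, 2, seed = s)$trials$direction,
              a$trials$direction), logical(1))
  expect_true(sum(others) == 0)
})

test_that("indivisible trial counts are rejected", {
  expect_error(session_schedule(10, 1), "divisible by 4")
  expect_error(session_schedule(8, 3), "n_blocks")
})

test_that("phase durations sum to the trial duration and onsets honor blocks", {
  sch <- session_schedule(8, 2, seed = 3, block_gap_s = 60)
  expect_equal(sum(sch$timing), 12)
  on <- sch$trials$onset_s
  expect_equal(diff(on)[1:3], rep(12, 3))        # within block 1
  expect_equal(on[5] - on[4], 12 + 60)           # block gap
})

test_that("schedules round-trip through the events file", {
  sch <- session_schedule(12, 2, seed = 7, block_gap_s = 30)
  path <- tempfile(fileext = ".tsv")
  write_schedule(sch, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(tab)[1:4],
               c("trial_index", "block", "direction", "frequency_hz"))
  expect_equal(tab$stimulus_onset_s - tab$prompt_onset_s, rep(1, 12))
  back <- read_schedule(path, block_gap_s = 30)
  expect_equal(back$trials$direction, sch$trials$direction)
  expect_equal(back$trials$onset_s, sch$trials$onset_s)
  expect_equal(back$timing, sch$timing)
})
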