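# Flicker stimulus sequences and balanced randomized session schedules.

#' Direction-to-frequency map of the four directional commands
#'
#' The fixed assignment of flicker frequencies to directional commands used
#' throughout the package: forward 10 Hz, backward 12 Hz, left 15 Hz,
#' right 20 Hz.
#'
#' @return Named numeric vector of stimulation frequencies in Hz, with names
#'   `forward`, `backward`, `left`, `right` (the canonical class order).
#' @export
#' @examples
#' direction_frequencies()
direction_frequencies <- function() {
  c(forward = 10, backward = 12, left = 15, right = 20)
}

#' Generate a sinusoidal flicker grayscale sequence
#'
#' Computes the frame-indexed grayscale values of a sinusoidal flicker
#' stimulus at frequency `freq` rendered on a display with refresh rate
#' `refresh`. Frame `i` (0-based) takes the value
#' `a * sin(2*pi*freq*i/refresh + pi/2) + b`, with `(a, b) = (0.5, 0.5)` for
#' high modulation depth (full 0..1 contrast) and `(0.149, 0.464)` for low
#' depth (reduced contrast around mid-gray, range 0.315..0.613).
#'
#' @param freq Stimulus frequency in Hz (> 0).
#' @param refresh Display refresh rate in Hz (> 0, default 60).
#' @param n_frames Number of frames to generate (>= 1).
#' @param depth Modulation depth, `"high"` (default) or `"low"`.
#' @return An object of class `flicker_sequence`: a list with `frequency`,
#'   `refresh`, `depth` and `values` (numeric vector of length `n_frames`,
#'   all within \[0, 1\], frame 0 first).
#' @export
#' @examples
#' s <- flicker_sequence(10, 60, 12)
#' s$values[1]      # frame 0 is 1.0 at high depth
flicker_sequence <- function(freq, refresh = 60, n_frames, depth = c("high", "low")) {
  depth <- match.arg(depth)
  check_scalar_pos(freq, "freq")
  check_scalar_pos(refresh, "refresh")
  if (!is_count(n_frames)) stopf("`n_frames` must be a positive integer")
  i <- seq_len(n_frames) - 1
  ab <- if (depth == "high") c(0.5, 0.5) else c(0.149, 0.464)
  values <- ab[1] * sin(2 * pi * freq * i / refresh + pi / 2) + ab[2]
  structure(
    list(frequency = freq, refresh = refresh, depth = depth, values = values),
    class = "flicker_sequence"
  )
}

#' @export
print.flicker_sequence <- function(x, ...) {
  cat(sprintf("<flicker_sequence> %g Hz @ %g Hz refresh, %s depth, %d frames, range [%.3f, %.3f]\n",
              x$frequency, x$refresh, x$depth, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Default trial phase durations
#'
#' Each 12 s trial consists of a 1 s directional prompt, 5 s of flicker
#' stimulation, a 4 s action (recall) period with a blank screen, and 2 s of
#' rest.
#'
#' @return Named numeric vector of phase durations in seconds
#'   (`prompt`, `stimulus`, `action`, `rest`).
#' @export
default_timing <- function() {
  c(prompt = 1, stimulus = 5, action = 4, rest = 2)
}

#' Build a balanced randomized session schedule
#'
#' Creates the trial list for one recording session: `n_trials` trials split
#' evenly over `n_blocks` blocks, with each of the four directional commands
#' occurring equally often and the order given by a seeded random
#' permutation. Directions map to flicker frequencies through
#' [direction_frequencies()]. A configurable rest gap separates blocks
#' (default 60 s, the between-block break of the protocol).
#'
#' @param n_trials Total number of trials; must be divisible by 4 and by
#'   `n_blocks` (default 100).
#' @param n_blocks Number of blocks (default 2).
#' @param timing Named numeric vector of phase durations in seconds with
#'   names `prompt`, `stimulus`, `action`, `rest` (default [default_timing()]).
#' @param block_gap_s Rest gap inserted between consecutive blocks, seconds
#'   (default 60).
#' @param seed Integer seed for the trial-order permutation; `NULL` uses the
#'   current RNG state.
#' @return An object of class `session_schedule`: a list with `trials` (a
#'   data.frame with columns `trial`, `block`, `direction`, `frequency_hz`,
#'   `onset_s`), `timing`, `n_blocks`, `block_gap_s` and `seed`. `onset_s` is
#'   the trial (prompt) onset from recording start; phases follow at the
#'   cumulative timing offsets.
#' @export
#' @examples
#' sched <- session_schedule(8, 1, seed = 1)
#' table(sched$trials$direction)
session_schedule <- function(n_trials = 100, n_blocks = 2,
                             timing = default_timing(),
                             block_gap_s = 60, seed = NULL) {
  if (!is_count(n_trials)) stopf("`n_trials` must be a positive integer")
  if (!is_count(n_blocks)) stopf("`n_blocks` must be a positive integer")
  if (n_trials %% 4 != 0)
    stopf("`n_trials` (%d) must be divisible by 4 (one count per direction)", n_trials)
  if (n_trials %% n_blocks != 0)
    stopf("`n_trials` (%d) must be divisible by `n_blocks` (%d)", n_trials, n_blocks)
  phases <- c("prompt", "stimulus", "action", "rest")
  if (!is.numeric(timing) || !all(phases %in% names(timing)))
    stopf("`timing` must be a named numeric vector with names %s",
          paste(phases, collapse = ", "))
  timing <- timing[phases]
  if (any(timing <= 0)) stopf("all phase durations must be positive")
  if (!is.numeric(block_gap_s) || length(block_gap_s) != 1L || block_gap_s < 0)
    stopf("`block_gap_s` must be a single non-negative number")

  dirs <- names(direction_frequencies())
  base <- rep(dirs, each = n_trials / 4)
  order <- with_seed(seed, sample.int(n_trials))
  direction <- base[order]
  trial_dur <- sum(timing)
  per_block <- n_trials / n_blocks
  block <- rep(seq_len(n_blocks), each = per_block)
  within <- (seq_len(n_trials) - 1) %% per_block
  onset <- (block - 1) * (per_block * trial_dur + block_gap_s) + within * trial_dur
  trials <- data.frame(
    trial = seq_len(n_trials),
    block = block,
    direction = direction,
    frequency_hz = unname(direction_frequencies()[direction]),
    onset_s = onset,
    stringsAsFactors = FALSE
  )
  structure(
    list(trials = trials, timing = timing, n_blocks = n_blocks,
         block_gap_s = block_gap_s, seed = seed),
    class = "session_schedule"
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %d trials in %d block(s), %g s/trial (%s)\n",
              nrow(x$trials), x$n_blocks, sum(x$timing),
              paste(sprintf("%s %g s", names(x$timing), x$timing), collapse = ", ")))
  print(table(direction = x$trials$direction))
  invisible(x)
}

#' Total duration of a scheduled session in seconds
#' @param schedule A [session_schedule()].
#' @return Duration in seconds from recording start to the end of the last
#'   trial's rest phase.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "session_schedule"))
  max(schedule$trials$onset_s) + sum(schedule$timing)
}

#' Write a session schedule as a tab-delimited events file
#'
#' One row per trial with columns `trial_index`, `block`, `direction`,
#' `frequency_hz`, then one onset column per phase
#' (`prompt_onset_s`, `stimulus_onset_s`, `action_onset_s`, `rest_onset_s`),
#' in that order.
#'
#' @param schedule A [session_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "session_schedule"))
  off <- cumsum(c(0, schedule$timing))[1:4]
  tr <- schedule$trials
  out <- data.frame(
    trial_index = tr$trial, block = tr$block, direction = tr$direction,
    frequency_hz = tr$frequency_hz,
    prompt_onset_s = tr$onset_s + off[1],
    stimulus_onset_s = tr$onset_s + off[2],
    action_onset_s = tr$onset_s + off[3],
    rest_onset_s = tr$onset_s + off[4]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a session schedule written by [write_schedule()]
#'
#' @param path Events file path.
#' @param block_gap_s Between-block gap to record on the restored object
#'   (default 60; the gap is implied by, not stored in, the onsets).
#' @return A [session_schedule()] object.
#' @export
read_schedule <- function(path, block_gap_s = 60) {
  if (!file.exists(path)) stopf("schedule file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("trial_index", "block", "direction", "frequency_hz",
            "prompt_onset_s", "stimulus_onset_s", "action_onset_s", "rest_onset_s")
  if (!all(need %in% names(tab)))
    stopf("schedule file lacks columns: %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  timing <- c(
    prompt = tab$stimulus_onset_s[1] - tab$prompt_onset_s[1],
    stimulus = tab$action_onset_s[1] - tab$stimulus_onset_s[1],
    action = tab$rest_onset_s[1] - tab$action_onset_s[1],
    rest = if (nrow(tab) > 1)
      min(tab$prompt_onset_s[2] - tab$rest_onset_s[1],
          tab$rest_onset_s[1] - tab$action_onset_s[1]) else
      tab$rest_onset_s[1] - tab$action_onset_s[1]
  )
  # rest duration from consecutive same-block trials when available
  same_block <- which(diff(tab$block) == 0)
  if (length(same_block))
    timing["rest"] <- tab$prompt_onset_s[same_block[1] + 1] - tab$rest_onset_s[same_block[1]]
  trials <- data.frame(
    trial = tab$trial_index, block = tab$block, direction = tab$direction,
    frequency_hz = tab$frequency_hz, onset_s = tab$prompt_onset_s,
    stringsAsFactors = FALSE
  )
  structure(
    list(trials = trials, timing = timing, n_blocks = length(unique(tab$block)),
         block_gap_s = block_gap_s, seed = NULL),
    class = "session_schedule"
  )
}
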