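# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

quiet <- function(expr) suppressWarnings(expr)

# small simulated session (8 trials, ground truth attached)
small_session <- function() {
  memoize("small_session", {
    sched <- session_schedule(8, 1, seed = 11)
    simulate_session(sched, sim_config(seed = 12), keep_sources = TRUE)
  })
}

# the 100-trial default-configuration benchmark run (seed 0)
benchmark_fit <- function() {
  memoize("benchmark_fit", {
    sched <- session_schedule(100, 2, seed = derive_seed0(0, 1))
    rec <- simulate_session(sched, sim_config(seed = derive_seed0(0, 2)))
    quiet(ssvep_decode(rec, seed = derive_seed0(0, 3)))
  })
}

# mirror of the package-internal sub-seed derivation, kept here so fixtures
# line up with run_pipeline(seed = 0)
derive_seed0 <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# epochs of the small session after the standard preprocessing chain
small_epochs <- function() {
  memoize("small_epochs", {
    p <- bandpass_filter(notch_filter(small_session(), 50), 8, 50)
    epoch_by_events(select_channels(p))
  })
}

# deterministic synthetic feature frame: four well-separated Gaussian
# clusters in 8-D, n rows per class, with trial bookkeeping
gaussian_features <- function(n_per_class = 50, sep = 6, seed = 1,
                              segs_per_trial = 5) {
  set.seed(seed)
  classes <- names(direction_frequencies())
  rows <- lapply(seq_along(classes), function(k) {
    mu <- rep(0, 8); mu[k] <- sep
    X <- matrix(rnorm(n_per_class * 8), ncol = 8) + rep(mu, each = n_per_class)
    X
  })
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("csp_", rep(c(10, 12, 15, 20), each = 2), "_", 1:2)
  n <- nrow(X)
  df <- cbind(as.data.frame(X),
              data.frame(label = factor(rep(classes, each = n_per_class),
                                        levels = classes),
                         trial = rep(seq_len(ceiling(n / segs_per_trial)),
                                     each = segs_per_trial)[seq_len(n)],
                         offset_s = 0))
  class(df) <- c("ssvep_features", "data.frame")
  df
}

# minimal XDF writer used as an independent construction of the container
# format (magic, varint-length chunks, stream-header XML, sample chunks)
write_test_xdf <- function(path, data, srate, labels, markers) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("XDF:", con, eos = NULL)
  chunk <- function(tag, payload) {
    len <- length(payload) + 2
    if (len < 256) {
      writeBin(as.raw(1), con); writeBin(as.raw(len), con)
    } else {
      writeBin(as.raw(4), con)
      writeBin(as.integer(len), con, size = 4, endian = "little")
    }
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(payload, con)
  }
  raw_int32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  # file header
  chunk(1, charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>"))
  # stream 1: EEG float32
  ch_xml <- paste0("<channel><label>", labels, "</label></channel>", collapse = "")
  hdr1 <- paste0("<?xml version=\"1.0\"?><info><name>EEG</name><type>EEG</type>",
                 "<channel_count>", nrow(data), "</channel_count>",
                 "<nominal_srate>", srate, "</nominal_srate>",
                 "<channel_format>float32</channel_format>",
                 "<desc><channels>", ch_xml, "</channels></desc></info>")
  chunk(2, c(raw_int32(1), charToRaw(hdr1)))
  # stream 2: markers (string, irregular rate)
  hdr2 <- paste0("<?xml version=\"1.0\"?><info><name>Markers</name>",
                 "<type>Markers</type><channel_count>1</channel_count>",
                 "<nominal_srate>0</nominal_srate>",
                 "<channel_format>string</channel_format></info>")
  chunk(2, c(raw_int32(2), charToRaw(hdr2)))
  # EEG samples chunk: first sample stamped at t=0, rest deduced
  pay <- c(raw_int32(1), as.raw(4), raw_int32(ncol(data)))
  for (s in seq_len(ncol(data))) {
    if (s == 1) {
      pay <- c(pay, as.raw(8), writeBin(0, raw(), size = 8, endian = "little"))
    } else pay <- c(pay, as.raw(0))
    pay <- c(pay, writeBin(as.numeric(data[, s]), raw(), size = 4,
                           endian = "little"))
  }
  chunk(3, pay)
  # marker samples chunk, each timestamped
  pay <- c(raw_int32(2), as.raw(1), as.raw(nrow(markers)))
  for (k in seq_len(nrow(markers))) {
    lab <- charToRaw(markers$label[k])
    pay <- c(pay, as.raw(8),
             writeBin(markers$time[k], raw(), size = 8, endian = "little"),
             as.raw(1), as.raw(length(lab)), lab)
  }
  chunk(3, pay)
  invisible(path)
}
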