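# Recording input/output: native (float32 + JSON header + events TSV),
# EDF (16-bit, write + read), XDF (read-only), and results writing.
#
# Native format, given stem `rec`:
#   rec.json        header: {"format": "ssvepbci/native", "version": 1,
#                   "sampling_rate": Hz, "n_channels", "n_samples",
#                   "channel_labels": [...], "dtype": "float32",
#                   "byte_order": "little"}
#   rec.bin         channel-major float32 little-endian (channel 1's S
#                   samples, then channel 2's, ...)
#   rec.events.tsv  tab-delimited: sample_index (0-based), label, trial

native_paths <- function(path) {
  stem <- sub("\\.json$", "", path)
  list(json = paste0(stem, ".json"), bin = paste0(stem, ".bin"),
       events = paste0(stem, ".events.tsv"))
}

write_events_tsv <- function(events, path) {
  utils::write.table(events[, c("sample_index", "label", "trial")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_index", "label", "trial") %in% names(ev)))
    stopf("events file %s lacks sample_index/label/trial columns", path)
  ev
}

#' Write a recording
#'
#' @param rec An [eeg_recording()].
#' @param path Output path: for `"native"` a stem (or the `.json` path);
#'   for `"edf"` the `.edf` file path (events are written to a
#'   `<path>.events.tsv` sidecar, since plain EDF stores no annotations).
#' @param format `"native"` (default) or `"edf"`.
#' @param physical_range For EDF, symmetric physical range in uV mapped to
#'   the 16-bit digital range; default the data's max absolute value.
#' @return The main written path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("native", "edf"),
                            physical_range = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "native") {
    p <- native_paths(path)
    header <- list(format = "ssvepbci/native", version = 1L,
                   sampling_rate = rec$srate, n_channels = n_channels(rec),
                   n_samples = n_samples(rec), channel_labels = rec$labels,
                   dtype = "float32", byte_order = "little")
    jsonlite::write_json(header, p$json, auto_unbox = TRUE, digits = NA)
    con <- file(p$bin, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
    write_events_tsv(rec$events, p$events)
    invisible(p$json)
  } else {
    write_edf(rec, path, physical_range)
    write_events_tsv(rec$events, paste0(path, ".events.tsv"))
    invisible(path)
  }
}

#' Read a recording
#'
#' @param path File path: native stem/`.json`, `.edf`, or `.xdf`.
#' @param format `"native"`, `"edf"` or `"xdf"` (default guessed from the
#'   extension).
#' @return An [eeg_recording()]. Channel labels are normalized to upper
#'   case. For EDF, events are loaded from a `<path>.events.tsv` sidecar
#'   when present. XDF support is read-only and limited to one regular-rate
#'   EEG stream plus one marker stream.
#' @export
read_recording <- function(path, format = c("auto", "native", "edf", "xdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else if (grepl("\\.xdf$", path, ignore.case = TRUE)) "xdf"
    else "native"
  }
  switch(format,
    native = read_native(path),
    edf = read_edf(path),
    xdf = read_xdf(path),
    stopf("unsupported format '%s'", format))
}

read_native <- function(path) {
  p <- native_paths(path)
  if (!file.exists(p$json)) stopf("native header not found: %s", p$json)
  h <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  if (!identical(h$format, "ssvepbci/native"))
    stopf("parse error in %s: not a native recording header", p$json)
  if (!is.numeric(h$sampling_rate) || h$sampling_rate <= 0)
    stopf("invalid sampling rate in %s", p$json)
  if (length(h$channel_labels) != h$n_channels)
    stopf("header channel count (%d) != label count (%d)",
          h$n_channels, length(h$channel_labels))
  if (!file.exists(p$bin)) stopf("native data file not found: %s", p$bin)
  need <- h$n_channels * h$n_samples
  con <- file(p$bin, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = need + 1, size = 4, endian = "little")
  if (length(vals) != need)
    stopf("parse error in %s at byte %d: expected %d float32 values, found %d",
          p$bin, 4 * min(length(vals), need), need, length(vals))
  data <- matrix(vals, nrow = h$n_channels, byrow = TRUE)
  events <- if (file.exists(p$events)) read_events_tsv(p$events) else empty_events()
  eeg_recording(data, h$sampling_rate, h$channel_labels, events)
}

# ---------------------------------------------------------------- EDF ----

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write an EDF file
#'
#' Plain EDF (16-bit integer samples, 1 s data records). All channels share
#' one symmetric physical range in uV; the last partial data record is
#' zero-padded. Events are not representable in plain EDF; see
#' [write_recording()] for the sidecar convention.
#'
#' @param rec An [eeg_recording()] with an integer number of samples per
#'   second.
#' @param path Output `.edf` path.
#' @param physical_range Symmetric physical range (uV); default
#'   `max(abs(data))` rounded up to 6 significant digits.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_range = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  srate <- rec$srate
  if (abs(srate - round(srate)) > 1e-9)
    stopf("EDF writer requires an integer sampling rate, got %g", srate)
  srate <- as.integer(round(srate))
  C <- n_channels(rec); S <- n_samples(rec)
  if (is.null(physical_range))
    physical_range <- signif(max(abs(rec$data), 1e-6) * 1.000001, 6)
  dig_max <- 32767L; dig_min <- -32768L
  n_rec <- ceiling(S / srate)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  # fixed header (256 bytes)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + C), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(C, 4)
  # per-signal header fields, each field for all signals consecutively
  for (lab in rec$labels) wr(paste("EEG", lab), 16)
  for (i in seq_len(C)) wr("AgAgCl electrode", 80)
  for (i in seq_len(C)) wr("uV", 8)
  for (i in seq_len(C)) wr(format(-physical_range, digits = 6), 8)
  for (i in seq_len(C)) wr(format(physical_range, digits = 6), 8)
  for (i in seq_len(C)) wr(dig_min, 8)
  for (i in seq_len(C)) wr(dig_max, 8)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr(srate, 8)
  for (i in seq_len(C)) wr("", 32)
  # data records: per record, per signal, srate int16 samples
  scale <- (dig_max - dig_min) / (2 * physical_range)
  padded <- cbind(rec$data, matrix(0, C, n_rec * srate - S))
  clipped <- pmin(pmax(padded, -physical_range), physical_range)
  dig <- round((clipped + physical_range) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    block <- dig[, (r - 1) * srate + seq_len(srate), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written with 16-bit integer samples
#'
#' Supports plain EDF with equal sampling rate across signals and 1 s (or
#' any fixed-duration) records. Physical values are reconstructed from each
#' signal's physical/digital ranges.
#'
#' @param path `.edf` path.
#' @return An [eeg_recording()]; events come from a `<path>.events.tsv`
#'   sidecar when present.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < width)
      stopf("parse error in %s: truncated header at byte %d", path,
            seek(con, where = NA))
    trimws(raw)
  }
  version <- rd(8)
  if (version != "0") stopf("parse error in %s at byte 0: not an EDF file", path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  if (is.na(C) || C < 1) stopf("parse error in %s: bad signal count", path)
  labels <- vapply(seq_len(C), function(i) rd(16), character(1))
  for (i in seq_len(C)) rd(80)      # transducer
  for (i in seq_len(C)) rd(8)       # dim
  phys_min <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(C), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(C)) rd(80)      # prefilter
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(C)) rd(32)
  if (length(unique(spr)) != 1)
    stopf("EDF reader supports a single sampling rate; got %s",
          paste(unique(spr), collapse = ", "))
  srate <- spr[1] / rec_dur
  data <- matrix(0, C, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    vals <- readBin(con, "integer", n = C * spr[1], size = 2,
                    endian = "little", signed = TRUE)
    if (length(vals) != C * spr[1])
      stopf("parse error in %s: truncated data record %d", path, r)
    block <- matrix(vals, nrow = spr[1])       # samples x channels
    data[, (r - 1) * spr[1] + seq_len(spr[1])] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- (data - dig_min) * gain + phys_min
  labels <- toupper(sub("^EEG ", "", labels))
  ev_path <- paste0(path, ".events.tsv")
  events <- if (file.exists(ev_path)) read_events_tsv(ev_path) else empty_events()
  events <- events[events$sample_index < ncol(data), , drop = FALSE]
  eeg_recording(data, srate, labels, events)
}

# ---------------------------------------------------------------- XDF ----

# Minimal XDF reader: one regular-rate numeric EEG stream + one string
# marker stream. Chunk layout: magic "XDF:", then chunks of
# [NumLengthBytes(1: 1|4|8)][length][tag(2, LE)][payload].

le_uint <- function(raw) sum(as.numeric(raw) * 256^(seq_along(raw) - 1))

#' Read an XDF file (one EEG stream + one marker stream)
#'
#' Minimal reader for the lab-streaming-layer container format: parses
#' stream headers (XML), sample chunks (float32/double64 numeric channels
#' or string markers) and timestamps, and converts marker timestamps to
#' 0-based sample indices on the EEG stream's clock. Clock-offset and
#' boundary chunks are skipped.
#'
#' @param path `.xdf` path.
#' @return An [eeg_recording()]; marker labels become events (their
#'   `trial` is parsed from a trailing `:<n>` suffix when present, else 0).
#' @export
read_xdf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 4 || rawToChar(raw[1:4]) != "XDF:")
    stopf("parse error in %s at byte 0: missing XDF magic", path)
  pos <- 5L  # 1-based next byte
  streams <- list()
  read_varlen <- function() {
    nb <- as.integer(raw[pos]); pos <<- pos + 1L
    if (!nb %in% c(1L, 4L, 8L))
      stopf("parse error in %s at byte %d: bad length size %d", path, pos - 2, nb)
    val <- le_uint(raw[pos:(pos + nb - 1)]); pos <<- pos + nb
    val
  }
  while (pos <= length(raw)) {
    len <- read_varlen()
    tag <- le_uint(raw[pos:(pos + 1)]); pos <- pos + 2L
    body_len <- len - 2
    body_start <- pos
    if (tag == 2) {            # StreamHeader: id + XML
      sid <- le_uint(raw[pos:(pos + 3)])
      xml <- rawToChar(raw[(pos + 4):(pos + body_len - 1)])
      doc <- xml2::read_xml(xml)
      info <- list(
        id = sid,
        type = xml2::xml_text(xml2::xml_find_first(doc, "//type")),
        n_chan = as.integer(xml2::xml_text(xml2::xml_find_first(doc, "//channel_count"))),
        srate = as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "//nominal_srate"))),
        format = xml2::xml_text(xml2::xml_find_first(doc, "//channel_format")),
        labels = xml2::xml_text(xml2::xml_find_all(doc, "//channels/channel/label")),
        samples = list(), stamps = numeric()
      )
      streams[[as.character(sid)]] <- info
      pos <- body_start + body_len
    } else if (tag == 3) {     # Samples
      sid <- le_uint(raw[pos:(pos + 3)]); pos <- pos + 4L
      st <- streams[[as.character(sid)]]
      if (is.null(st))
        stopf("parse error in %s at byte %d: samples for unknown stream %d",
              path, body_start, sid)
      nsb <- as.integer(raw[pos]); pos <- pos + 1L
      nsamp <- le_uint(raw[pos:(pos + nsb - 1)]); pos <- pos + nsb
      last_ts <- if (length(st$stamps)) st$stamps[length(st$stamps)] else 0
      for (s in seq_len(nsamp)) {
        tsb <- as.integer(raw[pos]); pos <- pos + 1L
        ts <- if (tsb == 8) {
          v <- readBin(raw[pos:(pos + 7)], "double", endian = "little")
          pos <- pos + 8L; v
        } else last_ts + (if (st$srate > 0) 1 / st$srate else 0)
        last_ts <- ts
        if (st$format == "string") {
          slen <- local({
            nb <- as.integer(raw[pos]); pos <<- pos + 1L
            v <- le_uint(raw[pos:(pos + nb - 1)]); pos <<- pos + nb; v
          })
          val <- if (slen > 0) rawToChar(raw[pos:(pos + slen - 1)]) else ""
          pos <- pos + slen
          st$samples[[length(st$samples) + 1L]] <- val
        } else {
          bytes <- switch(st$format, float32 = 4L, double64 = 8L,
                          stopf("unsupported XDF channel format '%s'", st$format))
          vals <- readBin(raw[pos:(pos + st$n_chan * bytes - 1)],
                          "numeric", n = st$n_chan, size = bytes,
                          endian = "little")
          pos <- pos + st$n_chan * bytes
          st$samples[[length(st$samples) + 1L]] <- vals
        }
        st$stamps <- c(st$stamps, ts)
      }
      streams[[as.character(sid)]] <- st
      pos <- body_start + body_len
    } else {
      pos <- body_start + body_len   # FileHeader / ClockOffset / Boundary / Footer
    }
  }
  is_marker <- vapply(streams, function(s) s$format == "string", logical(1))
  eeg <- streams[!is_marker]
  mrk <- streams[is_marker]
  if (length(eeg) != 1)
    stopf("expected exactly one numeric EEG stream, found %d", length(eeg))
  eeg <- eeg[[1]]
  data <- do.call(cbind, eeg$samples)     # channels x samples
  labels <- if (length(eeg$labels) == eeg$n_chan) eeg$labels
            else paste0("CH", seq_len(eeg$n_chan))
  t0 <- if (length(eeg$stamps)) eeg$stamps[1] else 0
  events <- empty_events()
  if (length(mrk) >= 1) {
    m <- mrk[[1]]
    if (length(m$samples)) {
      labs <- unlist(m$samples)
      trial <- suppressWarnings(as.integer(sub("^.*:(\\d+)$", "\\1", labs)))
      trial[is.na(trial)] <- 0L
      events <- data.frame(
        sample_index = as.integer(round((m$stamps - t0) * eeg$srate)),
        label = sub(":\\d+$", "", labs), trial = trial,
        stringsAsFactors = FALSE)
      events <- events[events$sample_index >= 0 &
                       events$sample_index < ncol(data), , drop = FALSE]
    }
  }
  eeg_recording(data, eeg$srate, labels, events)
}

# ------------------------------------------------------------- results ----

#' Write classification results
#'
#' Writes the 4 x 4 confusion matrix as CSV (row names = true classes) and
#' a schema-versioned metrics JSON with per-class, average and overall
#' accuracy.
#'
#' @param eval An `ssvep_eval` from [evaluate_classifier()], or a plain
#'   4 x 4 non-negative integer confusion matrix.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the classifier method or
#'   `"results"`).
#' @return Named character vector with the `metrics` and `confusion`
#'   paths, invisibly.
#' @export
write_results <- function(eval, dir, prefix = NULL) {
  if (inherits(eval, "ssvep_eval")) {
    confusion <- eval$confusion
    if (is.null(prefix)) prefix <- eval$method
    level <- eval$level
  } else {
    confusion <- eval
    if (is.null(prefix)) prefix <- "results"
    level <- "segment"
  }
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stopf("confusion must be a square matrix")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stopf("confusion entries must be non-negative integers")
  if (sum(confusion) == 0) stopf("confusion matrix has no samples")
  if (is.null(rownames(confusion)))
    rownames(confusion) <- colnames(confusion) <-
      names(direction_frequencies())[seq_len(nrow(confusion))]
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  metrics <- list(
    schema = "ssvepbci/metrics/1",
    level = level,
    n = sum(confusion),
    per_class_accuracy = as.list(per_class),
    average_accuracy = mean(per_class),
    overall_accuracy = sum(diag(confusion)) / sum(confusion)
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, paste0(prefix, "_metrics.json"))
  cpath <- file.path(dir, paste0(prefix, "_confusion.csv"))
  jsonlite::write_json(metrics, mpath, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(confusion), cpath, row.names = TRUE)
  invisible(c(metrics = mpath, confusion = cpath))
}

#' Read back a confusion CSV written by [write_results()]
#' @param path CSV path.
#' @return Integer matrix with class row/column names.
#' @export
read_confusion <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}
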