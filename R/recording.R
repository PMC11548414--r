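# EEG recording container: channels x samples matrix, sampling rate,
# 10-20 channel labels, and event markers.

#' Default 16-channel montage
#'
#' The 16 scalp electrodes of the recording montage, in acquisition order
#' (International 10-20 names, upper case).
#'
#' @return Character vector of 16 channel labels.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
    "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2")
}

#' The eight analysis channels
#'
#' The subset of the montage used for feature extraction and classification:
#' bilateral frontal, central, parietal and occipital sites.
#'
#' @return Character vector of 8 channel labels.
#' @export
analysis_channels <- function() {
  c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
}

#' Event label vocabulary
#'
#' Event markers use labels of the form `"<phase>/<direction>"` with phase in
#' `prompt`, `stimulus`, `action`, `rest` and direction in `forward`,
#' `backward`, `left`, `right`.
#'
#' @return Character vector of the 16 valid marker labels.
#' @export
event_vocabulary <- function() {
  as.vector(outer(c("prompt", "stimulus", "action", "rest"),
                  names(direction_frequencies()),
                  function(p, d) paste(p, d, sep = "/")))
}

empty_events <- function() {
  data.frame(sample_index = integer(), label = character(), trial = integer(),
             stringsAsFactors = FALSE)
}

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param srate Sampling rate in Hz (> 0).
#' @param labels Character vector of channel labels (length = `nrow(data)`);
#'   normalized to upper case.
#' @param events Data frame of event markers with columns `sample_index`
#'   (0-based sample offsets in `[0, n_samples)`), `label` (see
#'   [event_vocabulary()]), `trial` (integer). Defaults to no events.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, labels, events = empty_events()) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric channels x samples matrix")
  check_scalar_pos(srate, "srate")
  labels <- toupper(as.character(labels))
  if (length(labels) != nrow(data))
    stopf("channel count mismatch: %d data rows but %d labels",
          nrow(data), length(labels))
  if (anyDuplicated(labels)) stopf("duplicated channel labels")
  if (!is.data.frame(events) ||
      !all(c("sample_index", "label", "trial") %in% names(events)))
    stopf("`events` must be a data.frame with columns sample_index, label, trial")
  if (nrow(events)) {
    if (any(events$sample_index < 0 | events$sample_index >= ncol(data)))
      stopf("event sample indices must lie within [0, %d)", ncol(data))
  }
  rownames(data) <- labels
  structure(
    list(data = data, srate = as.numeric(srate), labels = labels,
         events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
              nrow(x$events)))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An [eeg_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Number of channels in a recording
#' @param rec An [eeg_recording()].
#' @return Integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$data)

# replace the data matrix, keeping metadata (shape-preserving ops)
#' @keywords internal
set_data <- function(rec, data) {
  stopifnot(identical(dim(data), dim(rec$data)))
  rec$data <- data
  rownames(rec$data) <- rec$labels
  rec
}
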