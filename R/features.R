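# Sliding-window segmentation and assembly of the labelled feature matrix.

#' Sliding-window segmentation of a signal slice
#'
#' Cuts a channels x samples slice into half-open windows of `width_s`
#' seconds advancing by `step_s` seconds, keeping every window that fits
#' entirely: offsets `0, step, 2*step, ...`, giving
#' `floor((T - width)/step) + 1` windows. Offsets are computed in samples
#' (`round(width_s*rate)`, `round(step_s*rate)`) so there is no float
#' drift; 0.5 s / 0.1 s at 250 Hz are exactly 125 / 25 samples.
#'
#' @param slice Channels x samples numeric matrix.
#' @param width_s Window width in seconds (> 0, at most the slice
#'   duration).
#' @param step_s Step between window starts in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @return List of channels x `round(width_s*rate)` matrices.
#' @export
sliding_windows <- function(slice, width_s = 0.5, step_s = 0.1, rate = 250) {
  if (!is.matrix(slice)) stopf("`slice` must be a channels x samples matrix")
  check_scalar_pos(width_s, "width_s")
  check_scalar_pos(step_s, "step_s")
  w <- round(width_s * rate)
  st <- max(1L, round(step_s * rate))
  S <- ncol(slice)
  if (w > S)
    stopf("window width %g s (%d samples) exceeds slice length (%d samples)",
          width_s, w, S)
  starts <- seq(0L, S - w, by = st)
  lapply(starts, function(s0) slice[, s0 + seq_len(w), drop = FALSE])
}

#' Extract the labelled feature matrix from trial epochs
#'
#' For every epoch, takes the bank's phase slice (after the bank's
#' per-frequency band filtering), segments it with the bank's windowing,
#' and computes each frequency's `2 m` log-variance CSP features. The row
#' layout is fixed: the 10 Hz filter pair, then 12, 15, 20 Hz
#' (`csp_<freq>_<p>` columns), one row per segment, labelled with the
#' trial's direction and provenance (`trial`, `offset_s`).
#'
#' @param epochs List of `trial_epoch` objects with the bank's channel
#'   count.
#' @param bank A fitted [fit_ovr_bank()].
#' @return An object of class `ssvep_features`: a data.frame with the
#'   `4 * 2m` feature columns plus `label` (factor in canonical direction
#'   order), `trial`, `offset_s`.
#' @export
extract_feature_matrix <- function(epochs, bank) {
  stopifnot(inherits(bank, "csp_bank"))
  if (!length(epochs)) stopf("`epochs` must be non-empty")
  if (nrow(epochs[[1]]$data) != bank$n_channels)
    stopf("channel mismatch: bank fitted on %d channels, epochs have %d",
          bank$n_channels, nrow(epochs[[1]]$data))
  dirs <- names(direction_frequencies())
  blocks <- vector("list", length(dirs))
  names(blocks) <- dirs
  meta <- NULL
  for (d in dirs) {
    segs <- segment_epochs_banded(epochs, bank$bands[[d]], bank$phase,
                                  bank$width_s, bank$step_s)
    feat <- t(vapply(segs$segments,
                     function(s) log_variance_features(s, bank$filters[[d]]),
                     numeric(2 * bank$m)))
    blocks[[d]] <- feat
    if (is.null(meta))
      meta <- data.frame(label = factor(segs$direction, levels = dirs),
                         trial = segs$trial, offset_s = segs$offset_s)
  }
  out <- do.call(cbind, blocks)
  colnames(out) <- bank$feature_names
  res <- cbind(as.data.frame(out), meta)
  class(res) <- c("ssvep_features", "data.frame")
  res
}

#' Feature column names of a feature matrix
#' @param features An `ssvep_features` data frame.
#' @return Character vector of the CSP feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("label", "trial", "offset_s"))
}

#' Write a feature matrix as CSV
#'
#' Columns: the `csp_<freq>_<p>` features, then `label`, `trial`,
#' `offset_s`.
#'
#' @param features An `ssvep_features` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
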