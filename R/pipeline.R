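# End-to-end offline decoding: filtering -> ICA cleaning -> one-vs-rest
# CSP features -> classification, wrapped in a single fitting function
# returning a classed result object.

#' Decode directional SSVEP commands from a recorded session
#'
#' Runs the full offline pipeline on a continuous recording:
#' 50 Hz zero-phase notch, 8-50 Hz band-pass, FastICA with automated
#' ocular-artifact removal, selection of the eight analysis channels,
#' epoching, a trial-level stratified 75:25 split, one-vs-rest CSP fitting
#' on the training trials, sliding-window log-variance feature extraction,
#' and classifier training/evaluation.
#'
#' The CSP bank is fitted on training trials only, so validation segments
#' never influence the spatial filters; `split_level = "segment"`
#' reproduces the alternative protocol in which individual windows are
#' split (optimistic because neighbouring windows overlap by 80%).
#'
#' @param rec An [eeg_recording()] with trial event markers.
#' @param methods Classifiers to train: subset of `c("lda","svm","mlp")`
#'   (default all three).
#' @param m CSP filter pairs per frequency (default 1 -> 8 features).
#' @param band_mode CSP band arrangement, `"per_frequency"` (default) or
#'   `"broadband"`; see [fit_ovr_bank()].
#' @param analysis_band Band used when `band_mode = "broadband"`
#'   (default `c(8, 30)`: alpha + beta).
#' @param phase Trial phase classified (default `"stimulus"`; `"action"`
#'   selects the post-stimulus recall window).
#' @param channels Analysis channel subset (default [analysis_channels()]).
#' @param timing Trial phase durations (default [default_timing()]).
#' @param split_level `"trial"` (default) or `"segment"`.
#' @param train_fraction Training fraction of the stratified split
#'   (default 0.75).
#' @param eval_level Evaluation granularity, `"segment"` (default) or
#'   `"trial"` (majority vote over a trial's segments).
#' @param use_ica Run the ICA artifact-removal stage (default `TRUE`).
#' @param ica_max_samples Maximum number of (evenly spaced) samples used to
#'   fit the ICA demixing matrix (default 50000, i.e. 200 s at 250 Hz);
#'   the fitted transforms are applied to the full recording.
#' @param ica_stage `"after_bandpass"` (default: notch -> band-pass ->
#'   ICA) or `"before_bandpass"` (notch -> ICA -> band-pass, where blink
#'   energy is still present for the flagging rule).
#' @param notch_hz Line frequency to notch (default 50).
#' @param acq_band Acquisition band-pass applied before feature
#'   extraction (default `c(8, 50)`).
#' @param width_s,step_s Segmentation window and step (defaults 0.5, 0.1).
#' @param seed Seed controlling the split and any stochastic classifier
#'   initialization.
#' @return An object of class `ssvep_decoding`: list with `evals` (named
#'   list of `ssvep_eval` per method), `models`, `bank`, `ica`
#'   (model + flag scores or `NULL`), `features`, `split`, `config`.
#' @export
ssvep_decode <- function(rec,
                         methods = c("lda", "svm", "mlp"),
                         m = 1,
                         band_mode = c("per_frequency", "broadband"),
                         analysis_band = c(8, 30),
                         phase = "stimulus",
                         channels = analysis_channels(),
                         timing = default_timing(),
                         split_level = c("trial", "segment"),
                         train_fraction = 0.75,
                         eval_level = c("segment", "trial"),
                         use_ica = TRUE, ica_max_samples = 50000,
                         ica_stage = c("after_bandpass", "before_bandpass"),
                         notch_hz = 50, acq_band = c(8, 50),
                         width_s = 0.5, step_s = 0.1,
                         seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  band_mode <- match.arg(band_mode)
  split_level <- match.arg(split_level)
  eval_level <- match.arg(eval_level)
  ica_stage <- match.arg(ica_stage)
  methods <- match.arg(methods, c("lda", "svm", "mlp"), several.ok = TRUE)

  proc <- notch_filter(rec, notch_hz)
  ica_info <- NULL
  run_ica <- function(r) {
    S <- ncol(r$data)
    fit_idx <- if (S > ica_max_samples)
      round(seq(1, S, length.out = ica_max_samples)) else seq_len(S)
    model <- fastica(r$data[, fit_idx, drop = FALSE],
                     seed = derive_seed(seed, 11L))
    fl <- flag_artifact_components(model, r)
    cleaned <- remove_components(r$data, model, fl$flagged)
    list(rec = set_data(r, cleaned),
         info = list(model = model, flagged = fl$flagged, scores = fl$scores))
  }
  if (use_ica && ica_stage == "before_bandpass") {
    res <- run_ica(proc); proc <- res$rec; ica_info <- res$info
  }
  proc <- bandpass_filter(proc, acq_band[1], acq_band[2])
  if (use_ica && ica_stage == "after_bandpass") {
    res <- run_ica(proc); proc <- res$rec; ica_info <- res$info
  }
  proc <- select_channels(proc, channels)
  epochs <- epoch_by_events(proc, timing)

  # split first (at the requested level), fit CSP on the training side only
  all_dirs <- vapply(epochs, `[[`, character(1), "direction")
  trial_ids <- vapply(epochs, `[[`, integer(1), "trial")
  skeleton <- data.frame(label = all_dirs, trial = trial_ids)
  split0 <- stratified_split(skeleton, train_fraction, level = "trial",
                             seed = derive_seed(seed, 23L))
  train_epochs <- epochs[skeleton$trial %in% split0$train_trials]
  bank <- fit_ovr_bank(train_epochs, m = m, band_mode = band_mode,
                       broadband = analysis_band, phase = phase,
                       width_s = width_s, step_s = step_s)
  features <- extract_feature_matrix(epochs, bank)

  if (split_level == "trial") {
    in_train <- features$trial %in% split0$train_trials
    split <- list(train = features[in_train, , drop = FALSE],
                  validation = features[!in_train, , drop = FALSE],
                  train_trials = split0$train_trials,
                  validation_trials = split0$validation_trials)
  } else {
    split <- stratified_split(features, train_fraction, level = "segment",
                              seed = derive_seed(seed, 23L))
  }

  models <- list(); evals <- list()
  for (meth in methods) {
    models[[meth]] <- train_classifier(split$train, meth,
                                       seed = derive_seed(seed, 31L))
    evals[[meth]] <- evaluate_classifier(models[[meth]], split$validation,
                                         level = eval_level)
  }
  structure(
    list(evals = evals, models = models, bank = bank, ica = ica_info,
         features = features, split = split,
         config = list(methods = methods, m = m, band_mode = band_mode,
                       analysis_band = analysis_band, phase = phase,
                       channels = channels, split_level = split_level,
                       train_fraction = train_fraction,
                       eval_level = eval_level, use_ica = use_ica,
                       ica_stage = ica_stage,
                       ica_max_samples = ica_max_samples,
                       notch_hz = notch_hz,
                       acq_band = acq_band, width_s = width_s,
                       step_s = step_s, seed = seed)),
    class = "ssvep_decoding"
  )
}

#' @export
print.ssvep_decoding <- function(x, ...) {
  cat(sprintf("<ssvep_decoding> %d segments (%d features), %s-level split, %s-level evaluation\n",
              nrow(x$features), length(feature_columns(x$features)),
              x$config$split_level, x$config$eval_level))
  for (meth in names(x$evals))
    cat(sprintf("  %-4s average accuracy %6.2f%%  (overall %6.2f%%)\n",
                toupper(meth), 100 * x$evals[[meth]]$average_accuracy,
                100 * x$evals[[meth]]$overall_accuracy))
  invisible(x)
}

#' @export
summary.ssvep_decoding <- function(object, ...) {
  print(object)
  if (!is.null(object$ica)) {
    cat(sprintf("ICA: %d component(s) flagged as ocular artifacts\n",
                length(object$ica$flagged)))
  }
  cat("\nCSP filter bank:\n")
  print(object$bank)
  for (meth in names(object$evals)) {
    cat(sprintf("\n%s confusion matrix (rows = truth):\n", toupper(meth)))
    print(object$evals[[meth]]$confusion)
  }
  invisible(object)
}

#' @export
coef.ssvep_decoding <- function(object, ...) {
  lapply(object$bank$filters,
         function(f) f$W[f$retained, , drop = FALSE])
}

#' Predict directions for a new recording
#'
#' Applies the fitted preprocessing, CSP bank and one trained classifier
#' to a new recording with event markers, returning one prediction per
#' trial (majority vote over segments).
#'
#' @param object A fitted [ssvep_decode()] result.
#' @param rec A new [eeg_recording()] on the same montage.
#' @param method Which trained classifier to use (default the first).
#' @param ... Unused.
#' @return Data frame with `trial`, `direction` (truth from the markers)
#'   and `predicted`.
#' @export
predict.ssvep_decoding <- function(object, rec, method = NULL, ...) {
  cfg <- object$config
  if (is.null(method)) method <- names(object$models)[1]
  proc <- notch_filter(rec, cfg$notch_hz)
  proc <- bandpass_filter(proc, cfg$acq_band[1], cfg$acq_band[2])
  if (!is.null(object$ica)) {
    cleaned <- remove_components(proc$data, object$ica$model, object$ica$flagged)
    proc <- set_data(proc, cleaned)
  }
  proc <- select_channels(proc, cfg$channels)
  epochs <- epoch_by_events(proc)
  feats <- extract_feature_matrix(epochs, object$bank)
  pred <- predict(object$models[[method]], feats)
  classes <- object$models[[method]]$classes
  agg <- tapply(seq_len(nrow(feats)), feats$trial, function(ix) {
    votes <- table(factor(as.character(pred[ix]), levels = classes))
    classes[which.max(votes)]
  })
  truth <- tapply(as.character(feats$label), feats$trial, `[`, 1)
  data.frame(trial = as.integer(names(agg)),
             direction = unname(truth), predicted = unname(agg),
             stringsAsFactors = FALSE)
}

#' Plot a confusion matrix
#'
#' Base-graphics heatmap of one classifier's confusion matrix with counts
#' overlaid.
#'
#' @param x A fitted [ssvep_decode()] result.
#' @param method Which classifier's matrix to draw (default the first).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.ssvep_decoding <- function(x, method = NULL, ...) {
  if (is.null(method)) method <- names(x$evals)[1]
  cm <- x$evals[[method]]$confusion
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True",
                  main = sprintf("%s confusion (avg acc %.1f%%)",
                                 toupper(method),
                                 100 * x$evals[[method]]$average_accuracy), ...)
  graphics::axis(1, seq_len(k), colnames(cm))
  graphics::axis(2, seq_len(k), rev(rownames(cm)), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k + 1 - i, cm[i, j])
  invisible(x)
}

#' Run the full simulate-and-decode pipeline
#'
#' Convenience wrapper used by the command-line interface: simulates a
#' session (or reads a recording), decodes it, and writes metrics JSON and
#' confusion CSV per classifier plus the feature matrix. All randomness
#' derives from `seed`, so two runs with the same arguments produce
#' byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_trials,n_blocks Schedule size (defaults 100 trials, 2 blocks).
#' @param recording Optional path to an existing recording (native/EDF/
#'   XDF); when `NULL` (default) a session is simulated with
#'   [sim_config()] defaults.
#' @param methods Classifiers to run (default all three).
#' @param write_features_csv Also write the feature matrix CSV
#'   (default TRUE).
#' @param ... Further arguments passed to [ssvep_decode()].
#' @return The [ssvep_decode()] result, invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 0, n_trials = 100, n_blocks = 2,
                         recording = NULL, methods = c("lda", "svm", "mlp"),
                         write_features_csv = TRUE, ...) {
  rec <- if (is.null(recording)) {
    sched <- session_schedule(n_trials, n_blocks, seed = derive_seed(seed, 1L))
    simulate_session(sched, sim_config(seed = derive_seed(seed, 2L)))
  } else read_recording(recording)
  fit <- ssvep_decode(rec, methods = methods, seed = derive_seed(seed, 3L), ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (meth in names(fit$evals)) write_results(fit$evals[[meth]], out_dir)
  if (write_features_csv)
    write_features(fit$features, file.path(out_dir, "features.csv"))
  write_csp_bank(fit$bank, file.path(out_dir, "csp_bank.json"))
  if (!is.null(fit$ica))
    utils::write.csv(fit$ica$scores, file.path(out_dir, "ica_components.csv"),
                     row.names = FALSE)
  invisible(fit)
}
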