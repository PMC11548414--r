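# Common spatial patterns: trace-normalized covariance averaging,
# generalized eigendecomposition of the two class covariances, log-variance
# features, and the one-vs-rest bank over the four stimulation frequencies.

#' Trace-normalized average covariance
#'
#' Averages `X_i X_i' / trace(X_i X_i')` over trials, so each trial
#' contributes equally regardless of its overall power; the result is
#' symmetric with unit trace.
#'
#' @param trials List of channels x samples matrices (all with the same
#'   channel count).
#' @return Symmetric channels x channels matrix with trace 1.
#' @export
normalized_covariance <- function(trials) {
  if (!is.list(trials) || length(trials) == 0)
    stopf("`trials` must be a non-empty list of channel x sample matrices")
  C <- nrow(trials[[1]])
  acc <- matrix(0, C, C)
  for (i in seq_along(trials)) {
    Xi <- trials[[i]]
    if (!is.matrix(Xi) || nrow(Xi) != C)
      stopf("trial %d is not a matrix with %d channels", i, C)
    cv <- Xi %*% t(Xi)
    tr <- sum(diag(cv))
    if (tr <= 0) stopf("trial %d has zero signal (trace 0)", i)
    acc <- acc + cv / tr
  }
  sig <- acc / length(trials)
  (sig + t(sig)) / 2
}

# ridge-regularize an SPD matrix if badly conditioned
#' @keywords internal
regularize_spd <- function(sigma, gamma = 1e-6, cond_limit = 1e10) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_limit) {
    C <- nrow(sigma)
    sigma <- (1 - gamma) * sigma + gamma * (sum(diag(sigma)) / C) * diag(C)
  }
  sigma
}

#' Fit a two-class CSP filter set
#'
#' Solves the generalized eigenproblem `Sigma_pos w = lambda Sigma_neg w`
#' via whitening of the composite covariance `Sigma_pos + Sigma_neg`: the
#' rows of the returned projection matrix `W` are the generalized
#' eigenvectors scaled so that `W (Sigma_pos + Sigma_neg) W' = I`, ordered
#' by the Rayleigh fraction
#' `lambda_pos_j = w_j' Sigma_pos w_j` (in (0, 1)) descending. The first
#' `m` and last `m` rows -- the filters maximizing variance for one class
#' and minimizing it for the other -- are the retained filters.
#'
#' Trial inputs may be given either as lists of channels x samples matrices
#' (covariances are computed with [normalized_covariance()]) or directly as
#' a pair of covariance matrices.
#'
#' @param pos,neg The two classes: lists of trial matrices, or single
#'   covariance matrices.
#' @param m Number of filter pairs to retain (default 1; `2 m <=` channel
#'   count).
#' @param gamma Ridge weight used only if a covariance is ill-conditioned.
#' @return An object of class `csp`: list with `W` (C x C, rows = filters,
#'   all generalized eigenvectors), `lambda` (eigenvalues `lambda_pos`,
#'   descending), `m`, `retained` (row indices of the 2 m retained
#'   filters), `sigma_pos`, `sigma_neg`.
#' @export
fit_csp <- function(pos, neg, m = 1, gamma = 1e-6) {
  sig_of <- function(x, what) {
    if (is.list(x)) normalized_covariance(x)
    else if (is.matrix(x) && nrow(x) == ncol(x)) (x + t(x)) / 2
    else stopf("`%s` must be a list of trials or a covariance matrix", what)
  }
  sp <- sig_of(pos, "pos")
  sn <- sig_of(neg, "neg")
  if (!all(dim(sp) == dim(sn))) stopf("class covariances differ in size")
  C <- nrow(sp)
  if (!is_count(m) || 2 * m > C)
    stopf("`m` must be a positive integer with 2*m <= %d channels", C)
  comp <- regularize_spd(sp + sn, gamma)
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= 0)
    stopf("composite covariance is not positive definite")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitener of comp
  Sw <- P %*% sp %*% t(P)
  es <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)    # descending lambda_pos
  W <- t(ec$vectors %*% diag(1 / sqrt(ec$values)) %*% es$vectors)
  # deterministic sign: largest-magnitude weight of each filter positive
  for (j in seq_len(C)) {
    w <- W[j, ]
    if (w[which.max(abs(w))] < 0) W[j, ] <- -w
  }
  retained <- c(seq_len(m), C - m + seq_len(m))
  structure(
    list(W = W, lambda = es$values, m = m, retained = retained,
         sigma_pos = sp, sigma_neg = sn),
    class = "csp"
  )
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("<csp> %d channels, m=%d | lambda+ range [%.3f, %.3f]\n",
              ncol(x$W), x$m, min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Log-variance CSP features of one segment
#'
#' Projects a segment through the retained filters and returns
#' `f_p = log( Var(y_p) / sum_i Var(y_i) )` over the `2 m` retained
#' projections, the classical normalized log-variance feature (the log
#' makes the feature distribution approximately normal). By construction
#' `sum(exp(f)) == 1`.
#'
#' @param segment Channels x samples matrix.
#' @param filters A fitted [fit_csp()] object.
#' @param var_floor Variance floor applied before the log (default 1e-12).
#' @return Numeric vector of `2 * filters$m` features.
#' @export
log_variance_features <- function(segment, filters, var_floor = 1e-12) {
  stopifnot(inherits(filters, "csp"))
  if (!is.matrix(segment) || nrow(segment) != ncol(filters$W))
    stopf("segment must have %d channels", ncol(filters$W))
  Y <- filters$W[filters$retained, , drop = FALSE] %*% segment
  v <- apply(Y, 1, stats::var)
  if (any(v < var_floor)) {
    warnf("zero-variance projection floored at %g", var_floor)
    v <- pmax(v, var_floor)
  }
  log(v / sum(v))
}

#' Fit the one-vs-rest CSP filter bank over the four target frequencies
#'
#' For each stimulation frequency, fits a two-class CSP with class "+" =
#' segments from trials at that frequency and class "-" = the pooled
#' segments of the other three frequencies. By default each frequency's
#' CSP operates on data band-passed narrowly around that frequency
#' (`f +/- half_bw` Hz, zero-phase Butterworth), the frequency-specific
#' arrangement used for SSVEP; `band_mode = "broadband"` instead fits all
#' four CSPs on a single `broadband` band.
#'
#' Training uses sliding-window segments of the selected phase of each
#' epoch (robust covariance averaging over many short segments).
#'
#' @param epochs List of `trial_epoch` objects (all four directions must be
#'   present).
#' @param m Filter pairs per frequency (default 1, giving `4 x 2m = 8`
#'   features).
#' @param band_mode `"per_frequency"` (default) or `"broadband"`.
#' @param half_bw Half-bandwidth in Hz of the per-frequency band
#'   (default 1).
#' @param broadband Band used when `band_mode = "broadband"`
#'   (default `c(8, 30)`).
#' @param phase Epoch phase to train on (default `"stimulus"`).
#' @param width_s,step_s Segmentation window width and step in seconds
#'   (defaults 0.5 and 0.1).
#' @return An object of class `csp_bank`: list with `filters` (named list
#'   of [fit_csp()] objects, one per frequency in 10/12/15/20 Hz order),
#'   `m`, `band_mode`, `bands` (per-frequency band edges), `phase`,
#'   `width_s`, `step_s`, `srate`, `n_channels`, `feature_names`.
#' @export
fit_ovr_bank <- function(epochs, m = 1, band_mode = c("per_frequency", "broadband"),
                         half_bw = 1, broadband = c(8, 30),
                         phase = "stimulus", width_s = 0.5, step_s = 0.1) {
  band_mode <- match.arg(band_mode)
  if (!length(epochs)) stopf("`epochs` must be non-empty")
  freqs <- direction_frequencies()
  have <- unique(vapply(epochs, `[[`, character(1), "direction"))
  missing <- setdiff(names(freqs), have)
  if (length(missing))
    stopf("missing direction(s): %s", paste(missing, collapse = ", "))
  srate <- epochs[[1]]$srate
  bands <- if (band_mode == "per_frequency")
    lapply(freqs, function(f) c(f - half_bw, f + half_bw))
  else lapply(freqs, function(f) broadband)
  names(bands) <- names(freqs)

  filters <- vector("list", length(freqs))
  names(filters) <- names(freqs)
  for (d in names(freqs)) {
    segs <- segment_epochs_banded(epochs, bands[[d]], phase, width_s, step_s)
    is_pos <- segs$direction == d
    filters[[d]] <- fit_csp(segs$segments[is_pos], segs$segments[!is_pos], m = m)
  }
  fn <- as.vector(vapply(freqs, function(f) paste0("csp_", f, "_", seq_len(2 * m)),
                         character(2 * m)))
  structure(
    list(filters = filters, m = m, band_mode = band_mode, bands = bands,
         phase = phase, width_s = width_s, step_s = step_s, srate = srate,
         n_channels = nrow(epochs[[1]]$data), feature_names = fn),
    class = "csp_bank"
  )
}

#' @export
print.csp_bank <- function(x, ...) {
  cat(sprintf("<csp_bank> 4 frequencies x %d filter pair(s) = %d features | %s bands | phase '%s'\n",
              x$m, 4 * 2 * x$m, x$band_mode, x$phase))
  for (d in names(x$filters))
    cat(sprintf("  %-8s %2g-%2g Hz  lambda+ = %s\n", d, x$bands[[d]][1],
                x$bands[[d]][2],
                paste(sprintf("%.3f", x$filters[[d]]$lambda[x$filters[[d]]$retained]),
                      collapse = " ")))
  invisible(x)
}

# filter each epoch in `band`, slice `phase`, and segment it; returns
# list(segments=list of matrices, direction, trial, offset_s)
#' @keywords internal
segment_epochs_banded <- function(epochs, band, phase, width_s, step_s) {
  srate <- epochs[[1]]$srate
  bt <- signal::butter(4, band / (srate / 2), type = "pass")
  segments <- list(); direction <- character(); trial <- integer(); offset <- numeric()
  for (ep in epochs) {
    filt <- t(apply(ep$data, 1, function(ch) filtfilt_reflect(bt$b, bt$a, ch)))
    ep2 <- ep; ep2$data <- filt
    sl <- phase_slice(ep2, phase)
    wins <- sliding_windows(sl, width_s, step_s, srate)
    segments <- c(segments, wins)
    k <- length(wins)
    direction <- c(direction, rep(ep$direction, k))
    trial <- c(trial, rep(ep$trial, k))
    offset <- c(offset, (seq_len(k) - 1) * step_s)
  }
  list(segments = segments, direction = direction, trial = trial,
       offset_s = offset)
}

#' Serialize a CSP bank to JSON
#'
#' Stores the projection matrices, eigenvalues and provenance (bands, m,
#' channel count, windowing) for reproducible reuse.
#'
#' @param bank A [fit_ovr_bank()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_csp_bank <- function(bank, path) {
  stopifnot(inherits(bank, "csp_bank"))
  obj <- list(
    schema = "ssvepbci/csp-bank/1", m = bank$m, band_mode = bank$band_mode,
    bands = bank$bands, phase = bank$phase, width_s = bank$width_s,
    step_s = bank$step_s, srate = bank$srate, n_channels = bank$n_channels,
    feature_names = bank$feature_names,
    filters = lapply(bank$filters, function(f)
      list(W = f$W, lambda = f$lambda, m = f$m, retained = f$retained))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
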