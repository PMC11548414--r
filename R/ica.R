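# FastICA decomposition and automated ocular-artifact removal.

#' Center and whiten a multichannel signal
#'
#' Subtracts each channel's mean and applies a whitening transform `K`
#' (computed from the eigendecomposition of the sample covariance) so that
#' the output rows have identity covariance.
#'
#' @param X Numeric channels x samples matrix with more samples than
#'   channels.
#' @param rank_tol Relative eigenvalue threshold below which the input is
#'   declared rank-deficient (default 1e-10).
#' @return List with `Z` (whitened channels x samples), `K` (whitening
#'   matrix, `Z = K %*% (X - mean)`), and `mean` (per-channel means).
#' @export
center_whiten <- function(X, rank_tol = 1e-10) {
  if (!is.matrix(X) || !is.numeric(X)) stopf("`X` must be a numeric matrix")
  if (!all(is.finite(X))) stopf("`X` must be finite")
  C <- nrow(X); S <- ncol(X)
  if (S <= C) stopf("need more samples (%d) than channels (%d)", S, C)
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- Xc %*% t(Xc) / (S - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < rank_tol * max(eg$values))
    stopf(paste("input is (near) rank-deficient: smallest covariance eigenvalue",
                "%.3g vs largest %.3g; reduce the channel dimension first"),
          min(eg$values), max(eg$values))
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  list(Z = K %*% Xc, K = K, mean = mu)
}

#' Fit a FastICA decomposition
#'
#' Symmetric (parallel) fixed-point FastICA maximizing non-Gaussianity
#' (negentropy) of the unmixed components. Each iteration applies the
#' fixed-point update
#' `w <- E[z g(w'z)] - E[g'(w'z)] w` to every weight vector, followed by
#' symmetric decorrelation (`W <- (W W')^{-1/2} W`), so the rows of the
#' demixing matrix converge jointly.
#'
#' @param X Channels x samples matrix.
#' @param n_components Number of components to extract (default all
#'   channels; must not exceed the channel count).
#' @param g Contrast nonlinearity, `"tanh"` (default) or `"cube"`.
#' @param tol Convergence tolerance on the weight-vector direction change
#'   (default 1e-5).
#' @param max_iter Maximum number of fixed-point iterations (default 500);
#'   non-convergence is recorded on the model as a warning, not an error.
#' @param seed Seed for the random orthonormal initialization.
#' @return An object of class `fastica`: list with `mixing`
#'   (channels x components), `demixing` (components x channels, acts on
#'   centered data), `whitening` (`K`), `mean`, `g`, `tol`, `max_iter`,
#'   `iterations`, `converged`, `seed`. Component sources have unit
#'   variance on the training data.
#' @export
fastica <- function(X, n_components = nrow(X), g = c("tanh", "cube"),
                    tol = 1e-5, max_iter = 500, seed = NULL) {
  g <- match.arg(g)
  if (!is.matrix(X)) stopf("`X` must be a matrix")
  if (!is_count(n_components) || n_components > nrow(X))
    stopf("`n_components` (%s) must be a positive integer <= channel count (%d)",
          format(n_components), nrow(X))
  cw <- center_whiten(X)
  # dimension reduction: keep the top-variance whitened directions
  cw$K <- cw$K[seq_len(n_components), , drop = FALSE]
  Z <- cw$K %*% (X - cw$mean)
  k <- n_components
  S <- ncol(Z)
  gfun <- switch(g,
    tanh = list(G = function(u) tanh(u), dG = function(u) 1 - tanh(u)^2),
    cube = list(G = function(u) u^3, dG = function(u) 3 * u^2))
  sym_decorrelate <- function(W) {
    sv <- eigen(W %*% t(W), symmetric = TRUE)
    sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-300)), k) %*%
      t(sv$vectors) %*% W
  }
  W <- with_seed(seed, matrix(stats::rnorm(k * nrow(Z)), k))
  W <- sym_decorrelate(W)
  iters <- max_iter
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- W %*% Z                              # k x S component estimates
    GU <- gfun$G(U)
    W1 <- GU %*% t(Z) / S - diag(rowMeans(gfun$dG(U)), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { iters <- it; converged <- TRUE; break }
  }
  if (!converged)
    warnf("FastICA did not converge in %d iterations (last delta %.2e)",
          max_iter, delta)
  demix_white <- W                         # components x whitened
  demixing <- demix_white %*% cw$K         # components x channels (centered)
  mixing <- MASS::ginv(demixing)           # channels x components
  structure(
    list(mixing = mixing, demixing = demixing, whitening = cw$K,
         mean = cw$mean, g = g, tol = tol, max_iter = max_iter,
         iterations = iters, converged = converged, seed = seed),
    class = "fastica"
  )
}

#' @export
print.fastica <- function(x, ...) {
  cat(sprintf("<fastica> %d components from %d channels | g=%s | %s in %d iteration(s)\n",
              nrow(x$demixing), ncol(x$demixing), x$g,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Unmix component source signals
#'
#' @param model A [fastica()] model.
#' @param X Channels x samples matrix on the model's channel set.
#' @return Components x samples matrix of source activations.
#' @export
ica_sources <- function(model, X) {
  stopifnot(inherits(model, "fastica"))
  if (nrow(X) != ncol(model$demixing))
    stopf("channel count mismatch: model has %d, data has %d",
          ncol(model$demixing), nrow(X))
  model$demixing %*% (X - model$mean)
}

#' Score and flag ocular-artifact components
#'
#' Each component is scored by the geometric mean of (i) its frontal
#' topography dominance -- the fraction of squared mixing weight carried by
#' the frontal channels -- and (ii) the fraction of its source power below
#' `lowfreq_hz` (Welch PSD). Both terms lie in \[0, 1\], so the score does
#' too; eye blinks load frontally and concentrate power below ~4 Hz, so
#' they score high. Components with score strictly greater than `threshold`
#' are flagged.
#'
#' @param model A [fastica()] model fitted on `rec`'s channels.
#' @param rec The [eeg_recording()] the model was fitted on (labels and
#'   sampling rate are taken from it).
#' @param frontal_labels Frontal channel set (default Fp1, Fp2, F7, F8).
#' @param threshold Flagging threshold in (0, 1\] (default 0.6).
#' @param lowfreq_hz Low-frequency cutoff in Hz for the spectral term
#'   (default 4).
#' @return List with `flagged` (integer component indices, possibly empty)
#'   and `scores` (data frame: `component`, `frontal_dominance`,
#'   `lowfreq_fraction`, `score`).
#' @export
flag_artifact_components <- function(model, rec,
                                     frontal_labels = c("FP1", "FP2", "F7", "F8"),
                                     threshold = 0.6, lowfreq_hz = 4) {
  stopifnot(inherits(model, "fastica"), inherits(rec, "eeg_recording"))
  frontal_labels <- toupper(frontal_labels)
  fidx <- match(frontal_labels, rec$labels)
  if (anyNA(fidx))
    stopf("frontal channel(s) %s not in recording (available: %s)",
          paste(frontal_labels[is.na(fidx)], collapse = ", "),
          paste(rec$labels, collapse = ", "))
  src <- ica_sources(model, rec$data)
  k <- nrow(src)
  frontal <- numeric(k); lowfrac <- numeric(k)
  for (j in seq_len(k)) {
    a <- model$mixing[, j]
    frontal[j] <- sum(a[fidx]^2) / sum(a^2)
    psd <- welch_psd(src[j, ], rec$srate,
                     nperseg = min(ncol(src), 4L * round(rec$srate)))
    lowfrac[j] <- sum(psd$power[psd$freq < lowfreq_hz]) / sum(psd$power)
  }
  score <- sqrt(frontal * lowfrac)
  list(
    flagged = which(score > threshold),
    scores = data.frame(component = seq_len(k), frontal_dominance = frontal,
                        lowfreq_fraction = lowfrac, score = score)
  )
}

#' Remove components and back-project
#'
#' Reconstructs the channel signals from all components except `indices`
#' (their activations are zeroed), then re-adds the channel means. Removing
#' nothing reproduces the input to numerical precision.
#'
#' @param X Channels x samples matrix on the model's channel set.
#' @param model A [fastica()] model.
#' @param indices Integer component indices to remove (may be empty).
#' @return Cleaned channels x samples matrix.
#' @export
remove_components <- function(X, model, indices = integer()) {
  stopifnot(inherits(model, "fastica"))
  k <- nrow(model$demixing)
  indices <- as.integer(indices)
  if (length(indices) && (any(indices < 1) || any(indices > k)))
    stopf("component indices out of range 1..%d", k)
  src <- ica_sources(model, X)
  if (length(indices)) src[indices, ] <- 0
  model$mixing %*% src + model$mean
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between `P = demixing %*%
#' mixing_true` and a scaled permutation matrix; 0 means perfect source
#' separation, larger is worse (normalized to \[0, 1\]-ish scale by the
#' standard row/column form).
#'
#' @param P Square matrix (estimated demixing times true mixing).
#' @return Non-negative scalar.
#' @export
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

#' Serialize a FastICA model to JSON
#'
#' @param model A [fastica()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ica_model <- function(model, path) {
  stopifnot(inherits(model, "fastica"))
  obj <- list(schema = "ssvepbci/ica-model/1",
              g = model$g, tol = model$tol, max_iter = model$max_iter,
              iterations = model$iterations, converged = model$converged,
              mean = model$mean,
              mixing = model$mixing, demixing = model$demixing,
              whitening = model$whitening)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a FastICA model written by [write_ica_model()]
#'
#' @param path JSON path.
#' @return A [fastica()] model.
#' @export
read_ica_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ssvepbci/ica-model/1"))
    stopf("not an ICA model file (schema: %s)", format(obj$schema))
  structure(
    list(mixing = as.matrix(obj$mixing), demixing = as.matrix(obj$demixing),
         whitening = as.matrix(obj$whitening), mean = as.numeric(obj$mean),
         g = obj$g, tol = obj$tol, max_iter = obj$max_iter,
         iterations = obj$iterations, converged = obj$converged, seed = NULL),
    class = "fastica"
  )
}
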