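rand_spd <- function(C) {
  M <- matrix(rnorm(C * C), C)
  M %*% t(M) + 0.05 * diag(C)
}

# independent route to the generalized eigenvalues lambda+ (Rayleigh
# fractions of sigma_pos against the composite covariance)
oracle_lambda <- function(sp, sn) {
  sort(Re(eigen(solve(sp + sn) %*% sp, only.values = TRUE)$values),
       decreasing = TRUE)
}

test_that("normalized covariance averages trace-normalized trial covariances", {
  set.seed(1)
  trials <- lapply(1:5, function(i) matrix(rnorm(4 * 100), 4))
  sig <- normalized_covariance(trials)
  expect_equal(sum(diag(sig)), 1, tolerance = 1e-10)
  expect_equal(sig, t(sig))
  one <- normalized_covariance(trials[1])
  cv <- trials[[1]] %*% t(trials[[1]])
  expect_equal(one, cv / sum(diag(cv)), tolerance = 1e-12)
  # repeating the same trial changes nothing
  expect_equal(normalized_covariance(trials[c(1, 1, 1)]), one)
  expect_error(normalized_covariance(list()), "non-empty")
  expect_error(normalized_covariance(list(matrix(0, 4, 10))), "zero signal")
})

test_that("white-noise covariance converges to I/C", {
  set.seed(2)
  trials <- lapply(1:50, function(i) matrix(rnorm(4 * 2000), 4))
  expect_true(max(abs(normalized_covariance(trials) - diag(4) / 4)) < 0.02)
})

test_that("CSP matches a direct generalized-eigensolver oracle", {
  set.seed(3)
  for (i in 1:10) {
    sp <- rand_spd(4); sn <- rand_spd(4)
    f <- fit_csp(sp, sn, m = 1)
    expect_lt(max(abs(f$lambda - oracle_lambda(sp, sn))), 1e-8)
    expect_lt(max(abs(f$W %*% (sp + sn) %*% t(f$W) - diag(4))), 1e-6)
    expect_true(all(f$lambda > 0 & f$lambda < 1))
    expect_true(all(diff(f$lambda) <= 1e-12))
  }
})

test_that("identical classes give lambda = 1/2 everywhere", {
  set.seed(4)
  trials <- lapply(1:6, function(i) matrix(rnorm(4 * 200), 4))
  f <- fit_csp(trials, trials, m = 2)
  expect_equal(f$lambda, rep(0.5, 4), tolerance = 1e-6)
})

test_that("a channel carrying the class difference dominates the top filter", {
  # class+ has 4x the variance on channel 1; channel 2 is common noise
  sp <- diag(c(4, 1)); sn <- diag(c(1, 1))
  sp <- sp / sum(diag(sp)); sn <- sn / sum(diag(sn))
  f <- fit_csp(sp, sn, m = 1)
  w <- abs(f$W[1, ])
  expect_gte(w[1] / w[2], 5)
})

test_that("CSP is equivariant under channel permutation", {
  set.seed(5)
  pos <- lapply(1:8, function(i) matrix(rnorm(4 * 300), 4) * c(2, 1, 1, 1))
  neg <- lapply(1:8, function(i) matrix(rnorm(4 * 300), 4))
  f1 <- fit_csp(pos, neg, m = 1)
  perm <- c(3, 1, 4, 2)
  f2 <- fit_csp(lapply(pos, function(x) x[perm, ]),
                lapply(neg, function(x) x[perm, ]), m = 1)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-8)
  # permuted-filter rows act identically on permuted data (up to sign)
  expect_equal(abs(f2$W[1, ]), abs(f1$W[1, perm]), tolerance = 1e-6)
})

test_that("class separation increases the top eigenvalue monotonically", {
  lam <- vapply(c(1, 2, 4, 8), function(r) {
    sp <- diag(c(r, 1)); sn <- diag(c(1, 1))
    fit_csp(sp / sum(diag(sp)), sn / sum(diag(sn)), m = 1)$lambda[1]
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
  expect_equal(lam[1], 0.5, tolerance = 1e-10)
})

test_that("log-variance features are normalized and scale-invariant", {
  set.seed(6)
  sp <- rand_spd(4); sn <- rand_spd(4)
  f <- fit_csp(sp, sn, m = 2)
  seg <- matrix(rnorm(4 * 125), 4)
  feats <- log_variance_features(seg, f)
  expect_length(feats, 4)
  expect_equal(sum(exp(feats)), 1, tolerance = 1e-10)
  expect_equal(log_variance_features(10 * seg, f), feats, tolerance = 1e-10)
  # equal projected variances -> both features log(1/2)
  fid <- fit_csp(diag(2) / 2, diag(2) / 2, m = 1)
  seg2 <- matrix(rnorm(2 * 4000, sd = 1), 2)
  fe <- log_variance_features(seg2, fid)
  expect_equal(fe, rep(log(0.5), 2), tolerance = 0.1)
})

test_that("the one-vs-rest bank yields 4 x 2m features and satisfies the identity", {
  epochs <- small_epochs()
  bank <- fit_ovr_bank(epochs, m = 1)
  expect_length(bank$feature_names, 8)
  bank2 <- fit_ovr_bank(epochs, m = 2)
  expect_length(bank2$feature_names, 16)
  for (f in bank$filters) {
    comp <- f$sigma_pos + f$sigma_neg
    expect_lt(max(abs(f$W %*% comp %*% t(f$W) - diag(nrow(comp)))), 1e-6)
  }
  # all four directions must be present
  sub <- epochs[vapply(epochs, `[[`, character(1), "direction") != "left"]
  expect_error(fit_ovr_bank(sub), "left")
})

test_that("CSP banks serialize to JSON with provenance", {
  bank <- fit_ovr_bank(small_epochs(), m = 1)
  path <- tempfile(fileext = ".json")
  write_csp_bank(bank, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$m, 1)
  expect_equal(obj$n_channels, 8)
  expect_named(obj$filters, names(direction_frequencies()))
})
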