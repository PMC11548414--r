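test_that("stratified segment split is exact for divisible classes", {
  fm <- gaussian_features(100, seed = 1, segs_per_trial = 1)
  sp <- stratified_split(fm, 0.75, level = "segment", seed = 2)
  expect_equal(as.vector(table(sp$train$label)), rep(75, 4))
  expect_equal(as.vector(table(sp$validation$label)), rep(25, 4))
  # partition: union of both sides is the input multiset
  both <- rbind(sp$train, sp$validation)
  expect_equal(both[order(both$csp_10_1), ], fm[order(fm$csp_10_1), ],
               ignore_attr = TRUE)
  sp2 <- stratified_split(fm, 0.75, level = "segment", seed = 2)
  expect_identical(sp$train, sp2$train)
})

test_that("trial-level split keeps whole trials together", {
  fm <- gaussian_features(50, seed = 3, segs_per_trial = 5)
  sp <- stratified_split(fm, 0.75, level = "trial", seed = 4)
  expect_length(intersect(unique(sp$train$trial),
                          unique(sp$validation$trial)), 0)
  expect_equal(sort(c(sp$train_trials, sp$validation_trials)),
               sort(unique(fm$trial)))
  # per-class trial fraction near 0.75
  tr_class <- tapply(as.character(fm$label), fm$trial, `[`, 1)
  frac <- table(tr_class[as.character(sp$train_trials)]) /
    table(tr_class)
  expect_true(all(abs(frac - 0.75) <= 0.15))
})

test_that("undersized classes are reported by name", {
  fm <- gaussian_features(10, seed = 5, segs_per_trial = 1)
  fm <- fm[!(fm$label == "left" & seq_len(nrow(fm)) %% 10 < 8), ]
  expect_error(stratified_split(fm, 0.75, level = "segment"), "left")
})

test_that("all three classifiers separate well-separated clusters perfectly", {
  fm <- gaussian_features(40, sep = 8, seed = 6)
  for (meth in c("lda", "svm", "mlp")) {
    model <- train_classifier(fm, meth, seed = 7)
    acc <- mean(predict(model, fm) == fm$label)
    expect_equal(acc, 1.0)
  }
})

test_that("permuted labels give chance-level validation accuracy", {
  accs <- vapply(1:10, function(s) {
    fm <- gaussian_features(40, sep = 8, seed = s)
    set.seed(1000 + s)
    fm$label <- sample(fm$label)
    sp <- stratified_split(fm, 0.75, level = "segment", seed = s)
    model <- train_classifier(sp$train, "lda", seed = s)
    ev <- evaluate_classifier(model, sp$validation)
    ev$overall_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.15)
  expect_lte(mean(accs), 0.35)
})

test_that("degenerate training inputs are rejected", {
  fm <- gaussian_features(20, seed = 8)
  expect_error(train_classifier(fm[fm$label == "forward", ], "lda"),
               "single class")
  expect_error(train_classifier(fm[0, ], "svm"), "empty")
  expect_error(train_classifier(fm, "boost"), "arg")
})

test_that("evaluation reports confusion counts and the unweighted class-mean accuracy", {
  fm <- gaussian_features(40, sep = 8, seed = 9)
  sp <- stratified_split(fm, 0.75, level = "trial", seed = 10)
  model <- train_classifier(sp$train, "svm", seed = 11)
  ev <- evaluate_classifier(model, sp$validation)
  expect_equal(unname(rowSums(ev$confusion)),
               as.vector(table(sp$validation$label)))
  expect_equal(ev$average_accuracy, mean(ev$per_class_accuracy))
  expect_equal(ev$overall_accuracy,
               sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(ev$average_accuracy, 1.0)

  # a constant predictor scores exactly chance on balanced validation
  const <- model
  const$fit <- NULL
  cm <- matrix(0L, 4, 4,
               dimnames = list(names(direction_frequencies()),
                               names(direction_frequencies())))
  cm[, 1] <- 25L
  per <- diag(cm) / rowSums(cm)
  expect_equal(mean(per), 0.25)
})

test_that("trial-level voting never scores below segment level on easy data", {
  fm <- gaussian_features(50, sep = 3, seed = 12, segs_per_trial = 5)
  sp <- stratified_split(fm, 0.75, level = "trial", seed = 13)
  model <- train_classifier(sp$train, "lda", seed = 14)
  seg <- evaluate_classifier(model, sp$validation, level = "segment")
  tri <- evaluate_classifier(model, sp$validation, level = "trial")
  expect_gte(tri$average_accuracy, seg$average_accuracy)
})

test_that("MLP training is seed-deterministic", {
  fm <- gaussian_features(30, sep = 4, seed = 15)
  m1 <- train_classifier(fm, "mlp", seed = 16)
  m2 <- train_classifier(fm, "mlp", seed = 16)
  expect_identical(predict(m1, fm), predict(m2, fm))
})
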