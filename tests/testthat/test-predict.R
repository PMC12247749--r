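test_that("dataset rows pair features at t with the event flag at t+1", {
  rec <- fake_record(10, event_pulses = 5)
  ds <- build_dataset(rec, 12)
  expect_equal(ds$n, 9L)
  expect_equal(which(ds$y == 1L), 4L)

  # shifting the event by one pulse moves exactly one label by one row
  ds2 <- build_dataset(fake_record(10, event_pulses = 6), 12)
  expect_equal(which(ds2$y == 1L), 5L)
  expect_equal(sum(ds$y != ds2$y), 2L)

  ds0 <- build_dataset(fake_record(130), 12)
  expect_equal(ds0$n, 129L)
  expect_true(all(ds0$y == 0L))

  ds20 <- build_dataset(rec, 20)
  expect_equal(ncol(ds20$X), 20L)
  expect_equal(colnames(ds20$X), feature_names(20))
  expect_error(build_dataset(list()), "no records")
})

test_that("under-sampling balances 1:1, seeded and deterministic", {
  rec <- fake_record(202, event_pulses = seq(10, 200, by = 2))
  ds <- build_dataset(rec, 12)
  bal <- undersample(ds, seed = 3)
  expect_equal(bal$n_pos, bal$n_neg)
  expect_equal(bal$n_pos, ds$n_pos)
  expect_identical(undersample(ds, seed = 3)$X, bal$X)
  expect_false(identical(undersample(ds, seed = 4)$X, bal$X))

  # already balanced input is unchanged up to ordering
  bal2 <- undersample(bal, seed = 5)
  expect_equal(bal2$n, bal$n)
  expect_error(undersample(build_dataset(fake_record(10), 12)), "classes")
})

test_that("oversampling duplicates positives to the negative count", {
  ds <- build_dataset(fake_record(50, event_pulses = c(10, 20)), 12)
  ov <- oversample(ds, seed = 1)
  expect_equal(ov$n_pos, ov$n_neg)
  expect_equal(ov$n_neg, ds$n_neg)
})

test_that("train/test split keeps the natural ratio in the test part", {
  rec <- fake_record(120, event_pulses = seq(10, 110, by = 10))
  ds <- build_dataset(rec, 12)
  sp <- train_test_split(ds, seed = 2)
  expect_equal(sp$train$n_pos, sp$train$n_neg)
  expect_lt(abs(sp$test$n_pos / sp$test$n - ds$n_pos / ds$n), 0.02)
})

test_that("LM training matches an exact logistic-regression oracle", {
  toy <- separable_toy(400, seed = 5)
  ds <- mbfus:::new_dataset(toy$X, toy$y, 12)
  model <- train_mlp(ds, train_config(epochs = 150, seed = 1))
  pr <- mlp_predict(model, toy$X)
  cm <- confusion_metrics(pr$positive, toy$y)
  expect_gte(cm$sensitivity, 0.99)

  oracle <- suppressWarnings(glm(y ~ ., family = binomial(),
                                 data = data.frame(toy$X, y = toy$y)))
  cm_o <- confusion_metrics(predict(oracle, type = "response") >= 0.5, toy$y)
  expect_gte(cm_o$sensitivity, 0.99)
  expect_gte(cm$accuracy, cm_o$accuracy - 0.02)
})

test_that("training is deterministic and handles one-class labels", {
  toy <- separable_toy(100, seed = 6)
  ds <- mbfus:::new_dataset(toy$X, toy$y, 12)
  m1 <- train_mlp(ds, train_config(epochs = 30, seed = 9))
  m2 <- train_mlp(ds, train_config(epochs = 30, seed = 9))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)

  ds0 <- mbfus:::new_dataset(toy$X, rep(0L, 100), 12)
  m0 <- train_mlp(ds0, train_config(epochs = 50, seed = 1))
  expect_true(all(mlp_predict(m0, toy$X)$prob < 0.5))
})

test_that("prediction applies the 0.5-or-greater rule and validates input", {
  m <- constant_model(0) # sigmoid(0) = 0.5 exactly
  pr <- mlp_predict(m, rep(0, 12))
  expect_equal(pr$prob, 0.5)
  expect_true(pr$positive)

  m49 <- constant_model(qlogis(0.49))
  expect_false(mlp_predict(m49, rep(0, 12))$positive)

  expect_error(mlp_predict(m, rep(0, 11)), "dimension")
  expect_error(mlp_predict(m, c(NA, rep(0, 11))), "finite")
})

test_that("confusion metrics reproduce the printed training ratios", {
  pred <- c(rep(1, 3244), rep(0, 142), rep(1, 246), rep(0, 3140))
  truth <- c(rep(1, 3244), rep(1, 142), rep(0, 246), rep(0, 3140))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$TP, 3244L)
  expect_equal(cm$FN, 142L)
  expect_equal(cm$FP, 246L)
  expect_equal(cm$TN, 3140L)
  expect_equal(cm$accuracy, 6384 / 6772)
  expect_equal(cm$sensitivity, 3244 / 3386)
  expect_equal(cm$precision, 3244 / 3490)
  expect_equal(cm$specificity, 3140 / 3386)

  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)

  allneg <- suppressWarnings(confusion_metrics(c(0, 0, 0), c(1, 0, 1)))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_true(is.nan(allneg$precision))
  w <- capture_warnings(confusion_metrics(c(0, 0), c(0, 0)))
  expect_true(any(grepl("undefined", w)))
  expect_error(confusion_metrics(integer(0), integer(0)), "non-empty")
})

test_that("metrics are algebraically consistent with the counts", {
  set.seed(8)
  for (i in 1:20) {
    p <- rbinom(50, 1, 0.5)
    a <- rbinom(50, 1, 0.3)
    cm <- suppressWarnings(confusion_metrics(p, a))
    n <- cm$TP + cm$FP + cm$TN + cm$FN
    expect_equal(n, 50L)
    expect_equal(cm$accuracy, (cm$TP + cm$TN) / n)
    if (!is.nan(cm$sensitivity)) {
      expect_equal(round(cm$sensitivity * (cm$TP + cm$FN)), cm$TP)
    }
  }
})

test_that("oversampling route trains a valid model behind the same interface", {
  ds <- build_dataset(small_corpus(30, seed = 55), 12)
  sp <- train_test_split(ds, seed = 1, balance = "oversample")
  m <- train_mlp(sp$train, train_config(epochs = 60, seed = 1))
  pr <- mlp_predict(m, sp$test$X)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  cm <- suppressWarnings(confusion_metrics(pr$positive, sp$test$y))
  expect_gte(cm$accuracy, 0.5)
})
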