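test_that("the RBF classifier separates separable data and scores consistently", {
  sep <- separable_data(n = 50, d = 4)
  xs <- fit_scaling(sep$x)
  model <- train_classifier(xs, sep$labels, cost = 8, gamma = 0.5)
  pred <- predict(model, xs, type = "class")
  expect_equal(as.character(pred), sep$labels)

  # deterministic predictions
  expect_identical(pred, predict(model, xs, type = "class"))

  # the continuous score agrees with the hard prediction by sign
  score <- predict(model, xs, type = "score")
  expect_equal(as.character(pred), ifelse(score > 0, "high", "low"))

  expect_error(train_classifier(xs, rep("high", 50)), "both classes")
})

test_that("metric formulas match direct evaluation of the defining equations", {
  rep <- compute_metrics(tp = 10, tn = 10, fp = 0, fn = 0)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$mcc, 1)

  expect_equal(compute_metrics(5, 5, 5, 5)$mcc, 0)

  # toy confusion, checked against a spreadsheet-style recomputation
  rep <- compute_metrics(tp = 48, tn = 42, fp = 12, fn = 6)
  expect_equal(rep$accuracy, 100 * (48 + 42) / 108)
  expect_equal(rep$sensitivity, 48 / 54)
  expect_equal(rep$specificity, 42 / 54)
  expect_equal(rep$mcc,
               (48 * 42 - 12 * 6) / sqrt(60 * 54 * 54 * 48))

  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(0, 5, 5, 0), "sensitivity undefined")
  expect_error(compute_metrics(5, 0, 0, 5), "specificity undefined")
})

test_that("swapping the classes exchanges sensitivity and specificity", {
  set.seed(17)
  for (i in 1:20) {
    cnt <- rpois(4, 20) + 1
    a <- compute_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- compute_metrics(cnt[2], cnt[1], cnt[4], cnt[3])
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    expect_equal(a$accuracy, b$accuracy)
    expect_equal(a$mcc, b$mcc)
  }
})

test_that("AUC equals exhaustive positive-negative pair counting", {
  labels <- rep(c("high", "low"), each = 5)
  expect_equal(roc_auc(c(6:10, 1:5), labels), 1)
  expect_equal(roc_auc(rep(1, 10), labels), 0.5)

  set.seed(23)
  for (i in 1:20) {
    n <- 20
    labels <- sample(rep(c("high", "low"), n / 2))
    scores <- sample(1:8, n, replace = TRUE)  # force some ties
    pos <- scores[labels == "high"]; neg <- scores[labels == "low"]
    wins <- 0
    for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(roc_auc(scores, labels), wins / (length(pos) * length(neg)))
  }
  expect_error(roc_auc(1:5, rep("high", 5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- sample(rep(c("high", "low"), 25))
  scores <- rnorm(50)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("low", "high"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels), ref)
})

test_that("complementing tie-free scores complements the AUC", {
  set.seed(29)
  labels <- sample(rep(c("high", "low"), 15))
  scores <- rnorm(30)
  expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
})

test_that("cross-validation pools fold confusions and is seed-deterministic", {
  sep <- separable_data(n = 40, d = 3)
  rep <- cross_validate(sep$x, sep$labels, k = 10, cost = 8, gamma = 0.5,
                        seed = 2)
  expect_equal(rep$accuracy, 100)
  expect_equal(with(rep$confusion, tp + tn + fp + fn), 40)

  rep2 <- cross_validate(sep$x, sep$labels, k = 10, cost = 8, gamma = 0.5,
                         seed = 2)
  expect_identical(attr(rep, "folds"), attr(rep2, "folds"))
  expect_equal(rep$auc, rep2$auc)

  # k = n degenerates to leave-one-out on a tiny balanced set
  tiny <- separable_data(n = 8, d = 2)
  loo <- cross_validate(tiny$x, tiny$labels, k = 8, cost = 8, gamma = 0.5)
  expect_equal(with(loo$confusion, tp + tn + fp + fn), 8)
  expect_equal(loo$accuracy, 100)

  expect_error(cross_validate(sep$x, rep(c("high", "low"), c(4, 36)), k = 10),
               "fewer members")
})

test_that("label-permuted cross-validation is calibrated near chance", {
  set.seed(41)
  accs <- replicate(20, {
    x <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(NULL, sprintf("F%d", 1:4)))
    labels <- sample(rep(c("high", "low"), 100))
    cross_validate(x, labels, k = 10, cost = 1, gamma = 0.25,
                   seed = sample.int(1e6, 1))$accuracy
  })
  expect_gt(mean(accs), 45)
  expect_lt(mean(accs), 55)
})

test_that("the stratified holdout split reproduces the 75/25 partition sizes", {
  labels <- rep(c("high", "low"), each = 108)
  x <- matrix(rnorm(216 * 3), 216, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[labels == "high", 1] <- x[labels == "high", 1] + 3
  h <- holdout_evaluate(x, labels, cost = 2, gamma = 0.3, seed = 11)
  expect_equal(h$train_n, 162)
  expect_equal(h$test_n, 54)
  expect_equal(sum(labels[h$train_idx] == "high"), 81)
  expect_identical(h$train_idx,
                   holdout_evaluate(x, labels, seed = 11)$train_idx)
})

test_that("jackknife regression recovers a noiseless monotone target", {
  ds <- generate_dataset(n_complexes = 40, n_properties = 6,
                         n_informative = 2, effect_size = 2,
                         pkd_noise_sd = 0, seed = 19)
  x <- encode_dataset(ds$records, ds$tables)[, ds$truth$informative]
  rep <- jackknife_regress(x, ds$records$pkd, cost = 64, gamma = 1,
                           epsilon = 0.01)
  expect_s3_class(rep, "regression_report")
  expect_lt(rep$mae, 0.3)
  expect_gt(rep$pearson_r, 0.95)
  expect_length(rep$predictions, 40)

  expect_error(jackknife_regress(x[1:2, ], ds$records$pkd[1:2]), "at least 3")
})

test_that("constant jackknife targets warn and still report the error", {
  set.seed(55)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(rep <- jackknife_regress(x, rep(5, 10), cost = 1,
                                          gamma = 0.3, epsilon = 0.1),
                 "constant")
  expect_true(is.nan(rep$pearson_r))
  expect_true(is.finite(rep$mae))
})
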