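test_that("metrics reproduce published-style confusion matrices to 2 dp", {
  proposed <- compute_metrics(confusion_matrix(tp = 73, tn = 84, fp = 6, fn = 17))
  expect_equal(round(proposed$acc, 2), 87.22)
  expect_equal(round(proposed$sn, 2), 81.11)
  expect_equal(round(proposed$sp, 2), 93.33)
  expect_equal(round(proposed$pr, 2), 92.41)
  expect_equal(round(proposed$mcc, 2), 0.75)

  ddm <- compute_metrics(confusion_matrix(tp = 67, tn = 80, fp = 10, fn = 23))
  expect_equal(round(ddm$acc, 2), 81.67)
  expect_equal(round(ddm$mcc, 2), 0.64)

  ep3 <- compute_metrics(confusion_matrix(tp = 41, tn = 90, fp = 0, fn = 49))
  expect_equal(round(ep3$sp, 2), 100)
  expect_equal(round(ep3$pr, 2), 100)
  expect_equal(round(ep3$mcc, 2), 0.54)
})

test_that("metric edge cases: perfect classifier, zero denominators", {
  perfect <- compute_metrics(confusion_matrix(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$mcc, 1)
  expect_warning(noneg <- compute_metrics(confusion_matrix(tp = 0, tn = 5,
                                                           fp = 0, fn = 5)),
                 "precision")
  expect_equal(noneg$pr, 0)
  expect_equal(noneg$mcc, 0)
  expect_error(confusion_matrix(0, 0, 0, 0), class = "mirtss_validation_error")
  expect_error(confusion_matrix(-1, 2, 0, 0), class = "mirtss_validation_error")
})

test_that("MCC symmetries: class swap invariant, label flip negates", {
  set.seed(53)
  for (trial in 1:20) {
    cm <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                  c("tp", "tn", "fp", "fn")))
    if (Reduce(`+`, cm) == 0) next
    m <- suppressWarnings(
      compute_metrics(confusion_matrix(cm$tp, cm$tn, cm$fp, cm$fn)))
    swap <- suppressWarnings(
      compute_metrics(confusion_matrix(cm$tn, cm$tp, cm$fn, cm$fp)))
    flip <- suppressWarnings(
      compute_metrics(confusion_matrix(cm$fn, cm$fp, cm$tn, cm$tp)))
    expect_equal(swap$mcc, m$mcc)
    expect_equal(flip$mcc, -m$mcc)
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
  }
})

test_that("random forest is deterministic and validates the feature manifest", {
  set.seed(59)
  fm <- rand_feature_matrix(n = 200, d = 10, informative = 4, shift = 3)
  model <- train_rf(fm, rf_config(seed = 5))
  pred_train <- predict(model, fm)
  expect_gte(mean(pred_train == fm$labels), 0.99)

  # single feature equal to the label separates perfectly
  one <- feature_matrix(cbind(S_only = c(rep(1, 10), rep(0, 10))),
                        c(rep(1L, 10), rep(0L, 10)))
  m1 <- train_rf(one, rf_config(num_trees = 20, seed = 2))
  expect_equal(predict(m1, one), one$labels)

  held <- rand_feature_matrix(n = 40, d = 10, informative = 4, shift = 3)
  again <- train_rf(fm, rf_config(seed = 5))
  expect_identical(predict(model, held), predict(again, held))

  renamed <- held$values
  colnames(renamed)[1] <- "S_unseen"
  expect_error(predict(model, renamed), "manifest",
               class = "mirtss_validation_error")
})

test_that("cross-validation is stratified, seeded and reproducible", {
  set.seed(61)
  fm <- rand_feature_matrix(n = 60, d = 6, informative = 3, shift = 3)
  cv1 <- cross_validate(fm, folds = 5, repeats = 2, rf_config(seed = 9))
  cv2 <- cross_validate(fm, folds = 5, repeats = 2, rf_config(seed = 9))
  expect_identical(cv1, cv2)
  expect_equal(cv1$criterion, c("Acc", "Sn", "Sp", "Pr", "MCC"))
  expect_true(all(cv1$sigma >= 0))
  expect_gte(cv1$mu[cv1$criterion == "Acc"], 90)

  expect_error(cross_validate(fm, folds = 61, repeats = 1),
               class = "mirtss_validation_error")
})

test_that("leave-one-out on ten samples runs and reports", {
  set.seed(67)
  fm <- rand_feature_matrix(n = 10, d = 3, informative = 1, shift = 4)
  cv <- suppressWarnings(
    cross_validate(fm, folds = 10, repeats = 1, rf_config(num_trees = 20)))
  expect_equal(nrow(cv), 5L)
  expect_true(all(is.finite(cv$mu)))
})

test_that("model save/load round-trip reproduces predictions", {
  set.seed(71)
  fm <- rand_feature_matrix(n = 40, d = 5, informative = 2, shift = 3)
  model <- train_rf(fm, rf_config(num_trees = 30, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict(back, fm), predict(model, fm))
})

test_that("sensitivity scan covers the parameter grid", {
  set.seed(73)
  fm <- rand_feature_matrix(n = 40, d = 6, informative = 3, shift = 3)
  scan <- rf_sensitivity_scan(fm, num_trees_grid = c(20L, 40L),
                              num_features_grid = c(2L, 3L),
                              folds = 4, repeats = 1)
  expect_equal(nrow(scan), 4L)
  expect_true(all(scan$acc_mu >= 0 & scan$acc_mu <= 100))
})
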