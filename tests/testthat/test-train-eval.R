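test_that("confusion counts match brute-force pair counting", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    truth <- sample(c("normal", "anomalous"), n, replace = TRUE)
    pred <- sample(c("normal", "anomalous"), n, replace = TRUE)
    cm <- confusion(truth, pred)
    for (a in c("normal", "anomalous")) for (b in c("normal", "anomalous")) {
      expect_equal(cm[a, b], sum(truth == a & pred == b))
    }
    expect_equal(sum(cm), n)
  }
})

test_that("confusion rejects malformed input", {
  expect_error(confusion(c("normal", "weird"), c("normal", "normal")),
               "weird")
  expect_error(confusion("normal", c("normal", "normal")), "equal length")
})

test_that("swapped predictions land on the off-diagonal", {
  cm <- confusion(c("normal", "anomalous"), c("anomalous", "normal"))
  expect_equal(diag(cm), c(normal = 0L, anomalous = 0L))
  expect_equal(cm["normal", "anomalous"], 1L)
  expect_equal(cm["anomalous", "normal"], 1L)
})

# golden values recomputed from the published hold-out confusion matrix
# (true-normal row 583/57, true-anomalous row 52/374)
test_that("metrics reproduce the conventional hold-out evaluation table", {
  rep <- metrics(confusion_from_counts(583, 57, 52, 374))
  r <- rep$rounded
  expect_equal(r$normal$recall, 91.09)
  expect_equal(r$normal$precision, 91.81)
  expect_equal(r$normal$f1, 91.45)
  expect_equal(r$anomalous$recall, 87.79)
  expect_equal(r$anomalous$f1, 87.28)
  # the matrix yields 86.77 (374/431 = 86.7749%); the source table prints
  # 86.78 — a rounding slip in the original, documented here
  expect_equal(r$anomalous$precision, 86.77)
  expect_lte(abs(r$anomalous$precision - 86.78), 0.0101)
  # overall accuracy from the matrix is 957/1066 = 89.77%, not the 89.51%
  # printed alongside it; the matrix is authoritative
  expect_equal(r$overall_accuracy, 89.77)
  expect_equal(rep$overall_accuracy, 100 * 957 / 1066)
})

# golden values from the record-disjoint evaluation matrix (241/194, 77/1288)
test_that("metrics reproduce the patient-wise evaluation table", {
  rep <- metrics(confusion_from_counts(241, 194, 77, 1288))
  r <- rep$rounded
  expect_equal(r$overall_accuracy, 84.94)
  expect_equal(r$normal$recall, 55.40)
  expect_equal(r$normal$precision, 75.79)
  expect_equal(r$normal$f1, 64.01)
  expect_equal(r$anomalous$recall, 94.36)
  expect_equal(r$anomalous$precision, 86.91)
  expect_equal(r$anomalous$f1, 90.48)
})

test_that("perfect predictions give 100 everywhere", {
  y <- c(rep("normal", 6), rep("anomalous", 4))
  rep <- metrics(confusion(y, y))
  expect_equal(rep$overall_accuracy, 100)
  for (cls in c("normal", "anomalous")) {
    expect_equal(rep$per_class[[cls]]$precision, 100)
    expect_equal(rep$per_class[[cls]]$recall, 100)
    expect_equal(rep$per_class[[cls]]$f1, 100)
  }
})

test_that("zero-denominator metrics are undefined, never silently zero", {
  # nothing predicted anomalous -> anomalous precision undefined
  rep <- metrics(confusion(c("normal", "anomalous"), c("normal", "normal")))
  expect_true(is.na(rep$per_class$anomalous$precision))
  expect_equal(rep$per_class$anomalous$recall, 0)
  # no true anomalous -> anomalous recall undefined
  rep2 <- metrics(confusion(c("normal", "normal"), c("normal", "anomalous")))
  expect_true(is.na(rep2$per_class$anomalous$recall))
})

test_that("metric identities hold on random matrices (property)", {
  set.seed(7)
  for (i in 1:25) {
    cm <- confusion_from_counts(sample(1:200, 1), sample(1:200, 1),
                                sample(1:200, 1), sample(1:200, 1))
    rep <- metrics(cm)
    for (cls in c("normal", "anomalous")) {
      p <- rep$per_class[[cls]]$precision / 100
      r <- rep$per_class[[cls]]$recall / 100
      expect_equal(rep$per_class[[cls]]$f1, 100 * 2 * p * r / (p + r),
                   tolerance = 1e-10)
    }
    # overall accuracy = prevalence-weighted mean of per-class recalls
    w <- rowSums(cm) / sum(cm)
    expect_equal(rep$overall_accuracy,
                 sum(w * c(rep$per_class$normal$recall,
                           rep$per_class$anomalous$recall)),
                 tolerance = 1e-10)
  }
})

test_that("patient-level flags equal a brute-force any() per record", {
  set.seed(12)
  for (i in 1:15) {
    n <- 80
    df <- data.frame(
      record_id = sample(sprintf("r%d", 1:8), n, replace = TRUE),
      label = sample(c("normal", "anomalous"), n, TRUE),
      predicted = sample(c("normal", "anomalous"), n, TRUE))
    agg <- aggregate_patient_level(df)
    for (r in unique(df$record_id)) {
      sub <- df[df$record_id == r, ]
      row <- agg$records[agg$records$record_id == r, ]
      expect_equal(row$flagged,
                   if (any(sub$predicted == "anomalous")) "anomalous"
                   else "normal")
      expect_equal(row$truth,
                   if (any(sub$label == "anomalous")) "anomalous"
                   else "normal")
    }
  }
})

test_that("patient-level recall never falls below segment-level recall", {
  set.seed(21)
  for (i in 1:20) {
    n <- 120
    df <- data.frame(
      record_id = sample(sprintf("r%d", 1:10), n, replace = TRUE),
      label = sample(c("normal", "anomalous"), n, TRUE, prob = c(0.4, 0.6)),
      predicted = sample(c("normal", "anomalous"), n, TRUE))
    seg_recall <- 100 * sum(df$label == "anomalous" &
                              df$predicted == "anomalous") /
      sum(df$label == "anomalous")
    pat <- aggregate_patient_level(df)
    expect_gte(pat$recall_anomalous, seg_recall)
  }
})

test_that("a single flagged segment alerts the whole record", {
  df <- data.frame(record_id = "r1",
                   label = c("anomalous", "anomalous", "anomalous"),
                   predicted = c("normal", "normal", "anomalous"))
  agg <- aggregate_patient_level(df)
  expect_equal(agg$records$flagged, "anomalous")
  expect_equal(agg$recall_anomalous, 100)
})

test_that("one-epoch training returns a finite single-row history", {
  ds <- make_toy_dataset(6, 6, seg_len = 240, seed = 31)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 2)
  m <- build_model(tiny_model_config(240), seed = 2)
  fit <- train_network(m, ds$samples[1:8, ], ds$label[1:8],
                       ds$samples[9:12, ], ds$label[9:12], cfg)
  expect_equal(nrow(fit$history), 1)
  expect_true(all(is.finite(unlist(fit$history))))
  expect_true(all(fit$history$train_acc >= 0 & fit$history$train_acc <= 100))
  expect_true(fit$model$trained)
})

test_that("training rejects shape mismatches and single-class pools", {
  ds <- make_toy_dataset(4, 4, seg_len = 240)
  cfg <- train_config(epochs = 1, seed = 1)
  m <- build_model(tiny_model_config(360), seed = 1)
  expect_error(train_network(m, ds$samples, ds$label, ds$samples, ds$label,
                             cfg), "expects 360")
  m2 <- build_model(tiny_model_config(240), seed = 1)
  expect_error(train_network(m2, ds$samples[1:4, ],
                             rep("normal", 4), ds$samples, ds$label, cfg),
               "both classes")
})

test_that("identical seeds reproduce identical training histories", {
  ds <- make_toy_dataset(10, 10, seg_len = 240, seed = 5)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 77)
  run <- function() {
    m <- build_model(tiny_model_config(240), seed = 77)
    train_network(m, ds$samples[1:14, ], ds$label[1:14],
                  ds$samples[15:20, ], ds$label[15:20], cfg)$history
  }
  expect_identical(run(), run())
})

test_that("a separable toy task is learned far beyond chance", {
  ds <- make_toy_dataset(40, 40, seg_len = 240, seed = 9)
  fit <- train_on_pool(ds, tiny_model_config(240),
                       train_config(epochs = 8, batch_size = 16, seed = 3))
  final_acc <- fit$history$val_acc[nrow(fit$history)]
  # majority baseline on the balanced pool is 50%
  expect_gte(final_acc, 80)
})

test_that("prediction output is a tidy frame with the anomalous tie rule", {
  ds <- make_toy_dataset(5, 5, seg_len = 240, seed = 13)
  m <- build_model(tiny_model_config(240), seed = 5)
  pred <- predict_segments(m, ds)
  expect_equal(nrow(pred), 10)
  expect_true(all(abs(pred$p_normal + pred$p_anomalous - 1) < 1e-9))
  expect_true(all(pred$predicted[pred$p_anomalous > pred$p_normal] ==
                    "anomalous"))
  expect_true(all(pred$predicted[pred$p_anomalous < pred$p_normal] ==
                    "normal"))
  # batch vs one-by-one inference agree
  one_by_one <- do.call(rbind, lapply(1:4, function(i)
    predict_segments(m, ds$samples[i, , drop = FALSE])))
  expect_equal(one_by_one$p_anomalous, pred$p_anomalous[1:4],
               tolerance = 1e-12)
  expect_error(predict_segments(m, matrix(0L, 1, 100)), "expects 240")
})

test_that("cross-validation summaries agree with per-fold recomputation", {
  ds <- make_toy_dataset(12, 12, seg_len = 240, seed = 17)
  cfg <- train_config(epochs = 1, batch_size = 8, seed = 5, k = 2)
  cv <- cross_validate(ds, tiny_model_config(240), cfg)
  expect_equal(nrow(cv$folds), 2)
  expect_equal(cv$summary$accuracy[1], mean(cv$folds$accuracy))
  expect_equal(cv$summary$accuracy[2], sd(cv$folds$accuracy))
  expect_equal(cv$summary$loss[1], mean(cv$folds$loss))
  # every id validated exactly once
  plan <- make_folds(ds, k = 2, seed = 5)
  expect_equal(unname(tabulate(plan$ids$fold, 2)), c(12L, 12L))
})
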