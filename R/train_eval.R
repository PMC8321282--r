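# Training protocol and evaluation: seeded mini-batch training with a
# 70/30 train/validation monitor, k-fold cross-validation, confusion-matrix
# metrics (accuracy, precision, recall, F1 treating each class in turn as
# positive) and the patient-level alerting rule (a recording is flagged as
# soon as one of its windows is predicted anomalous).

#' Training configuration
#'
#' @param epochs full passes over the training set (default 200, matching the
#'   published protocol; scale down for smoke runs).
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param val_fraction share of the pool held out as the validation monitor
#'   when [train_on_pool()] makes the split itself (default 0.3).
#' @param seed integer seed covering shuffling, dropout and weight init.
#' @param k folds for [cross_validate()] (default 10).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L,
                         learning_rate = 1e-3, val_fraction = 0.3,
                         seed = 1L, k = 10L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            val_fraction > 0, val_fraction < 1, k >= 2)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 optimizer = "adam", loss = "categorical_crossentropy",
                 seed = as.integer(seed), k = as.integer(k)),
            class = "train_config")
}

eval_batched <- function(model, X, y_onehot, batch_size = 64L) {
  n <- dim(X)[1L]
  loss_sum <- 0
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    fwd <- model_forward(model, X[ix, , , drop = FALSE], training = FALSE)
    p <- fwd$probs
    loss_sum <- loss_sum - sum(y_onehot[ix, , drop = FALSE] * log(p + 1e-12))
    pred_anom <- p[, 2L] >= p[, 1L]
    correct <- correct + sum(pred_anom == (y_onehot[ix, 2L] == 1))
  }
  list(loss = loss_sum / n, accuracy = 100 * correct / n)
}

#' Train a network on prepared tensors
#'
#' Seeded mini-batch Adam on the categorical cross-entropy (plus the dense
#' layer's L2 penalty). Each epoch reshuffles the training set, updates
#' batch-norm running statistics, and logs loss and accuracy on both the
#' training and validation sets (validation in inference mode: dropout off,
#' running batch-norm moments).
#'
#' @param model an [build_model()] handle.
#' @param x_train,y_train training samples (matrix, one row per segment, in
#'   the units the model config expects raw ADC rows for) and labels.
#' @param x_val,y_val validation samples and labels.
#' @param cfg a [train_config()].
#' @return A list `(model, history)`; `history` is a data frame with one row
#'   per epoch: `epoch, train_loss, val_loss, train_acc, val_acc` (accuracies
#'   in percent).
#' @export
train_network <- function(model, x_train, y_train, x_val, y_val,
                          cfg = train_config()) {
  stopifnot(inherits(model, "ecg_cnn"), inherits(cfg, "train_config"))
  if (ncol(x_train) != model$config$input_length) {
    stop(sprintf("segments have %d samples but the model expects %d",
                 ncol(x_train), model$config$input_length), call. = FALSE)
  }
  y_tr <- labels_to_onehot(y_train)
  if (any(colSums(y_tr) == 0)) {
    stop("training set must contain both classes", call. = FALSE)
  }
  Xtr <- segments_to_input(x_train, model$config)
  Xva <- segments_to_input(x_val, model$config)
  y_va <- labels_to_onehot(y_val)
  n <- nrow(x_train)
  state <- adam_init(model)
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(n)
      loss_sum <- 0
      correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ix <- perm[start:min(start + cfg$batch_size - 1L, n)]
        fwd <- model_forward(model, Xtr[ix, , , drop = FALSE], training = TRUE)
        bwd <- model_backward(model, fwd, y_tr[ix, , drop = FALSE])
        model <- update_running_stats(model, fwd)
        up <- adam_step(model, bwd, state, cfg$learning_rate)
        model <- up$model
        state <- up$state
        loss_sum <- loss_sum + bwd$loss * length(ix)
        pred_anom <- fwd$probs[, 2L] >= fwd$probs[, 1L]
        correct <- correct + sum(pred_anom == (y_tr[ix, 2L] == 1))
      }
      val <- eval_batched(model, Xva, y_va)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = loss_sum / n,
                                  val_loss = val$loss,
                                  train_acc = 100 * correct / n,
                                  val_acc = val$accuracy)
    }
  })
  model$trained <- TRUE
  list(model = model, history = do.call(rbind, hist))
}

#' Train on a balanced pool with an internal stratified 70/30 monitor split
#'
#' Convenience wrapper: splits the pool per class into training and
#' validation shares ([split_segmentwise()]), then runs [train_network()].
#'
#' @param pool a [segment_dataset()] (typically the balanced training pool).
#' @param model_cfg a [model_config()].
#' @param cfg a [train_config()].
#' @return A list `(model, history, split)`.
#' @export
train_on_pool <- function(pool, model_cfg = model_config(),
                          cfg = train_config()) {
  stopifnot(inherits(pool, "segment_dataset"))
  split <- split_segmentwise(pool, train_fraction = 1 - cfg$val_fraction,
                             val_fraction = cfg$val_fraction, seed = cfg$seed)
  i_tr <- match_manifest(pool, split$train)
  i_va <- match_manifest(pool, split$validation)
  model <- build_model(model_cfg, seed = cfg$seed)
  fit <- train_network(model, pool$samples[i_tr, , drop = FALSE],
                       pool$label[i_tr],
                       pool$samples[i_va, , drop = FALSE],
                       pool$label[i_va], cfg)
  c(fit, list(split = split))
}

#' Per-segment class probabilities and predicted labels
#'
#' @param model a trained `ecg_cnn`.
#' @param segments a [segment_dataset()] or a bare sample matrix (raw ADC
#'   rows; unit handling follows the model config).
#' @param batch_size inference batch size.
#' @return A data frame with `p_normal`, `p_anomalous`, `predicted`
#'   (a probability tie goes to `anomalous`: missing a true anomaly costs
#'   more than a false alert), plus provenance columns when a dataset is
#'   given.
#' @export
predict_segments <- function(model, segments, batch_size = 64L) {
  stopifnot(inherits(model, "ecg_cnn"))
  ds <- NULL
  if (inherits(segments, "segment_dataset")) {
    ds <- segments
    segments <- ds$samples
  }
  if (ncol(segments) != model$config$input_length) {
    stop(sprintf("segments have %d samples but the model expects %d",
                 ncol(segments), model$config$input_length), call. = FALSE)
  }
  X <- segments_to_input(segments, model$config)
  n <- nrow(segments)
  probs <- matrix(NA_real_, n, 2L)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    probs[ix, ] <- model_forward(model, X[ix, , , drop = FALSE],
                                 training = FALSE)$probs
  }
  out <- data.frame(p_normal = probs[, 1L], p_anomalous = probs[, 2L],
                    predicted = factor(
                      ifelse(probs[, 2L] >= probs[, 1L],
                             "anomalous", "normal"),
                      levels = c("normal", "anomalous")))
  if (!is.null(ds)) {
    out <- cbind(data.frame(record_id = ds$record_id,
                            segment_index = ds$segment_index,
                            label = ds$label), out)
  }
  out
}

#' 2x2 confusion matrix of true vs predicted labels
#'
#' @param truth,predicted vectors (character or factor) over
#'   `{normal, anomalous}` of equal length.
#' @return An object of class `ecg_confusion`: an integer matrix with rows =
#'   true class, columns = predicted class.
#' @export
confusion <- function(truth, predicted) {
  lv <- c("normal", "anomalous")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), lv)
  if (length(bad) > 0L) {
    stop(sprintf("labels outside {normal, anomalous}: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  m <- table(factor(truth, lv), factor(predicted, lv))
  structure(matrix(as.integer(m), 2L, 2L, dimnames = list(
    truth = lv, predicted = lv)), class = c("ecg_confusion", "matrix"))
}

#' Build a confusion matrix directly from its four counts
#'
#' @param nn,na,an,aa counts: true-normal predicted-normal, true-normal
#'   predicted-anomalous, true-anomalous predicted-normal, true-anomalous
#'   predicted-anomalous.
#' @return An `ecg_confusion` matrix.
#' @export
confusion_from_counts <- function(nn, na, an, aa) {
  counts <- c(nn, na, an, aa)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  lv <- c("normal", "anomalous")
  structure(matrix(as.integer(c(nn, an, na, aa)), 2L, 2L,
                   dimnames = list(truth = lv, predicted = lv)),
            class = c("ecg_confusion", "matrix"))
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-class classification metrics from a confusion matrix
#'
#' Treats each class in turn as positive: with TP, TN, FP, FN the per-class
#' counts, accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP), recall
#' = TP/(TP+FN) and F1 = 2TP/(2TP+FP+FN). Overall accuracy is the diagonal
#' share. A metric whose denominator is zero is reported `NA` (undefined),
#' never silently 0. Values are percentages; `$rounded` holds the 2-dp
#' half-up presentation copies, full precision is retained in `$per_class`
#' and `$overall_accuracy`.
#'
#' @param cm an `ecg_confusion` matrix.
#' @return An object of class `metrics_report`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "ecg_confusion"))
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  lv <- rownames(cm)
  per <- lapply(seq_along(lv), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    prec <- safe(tp, tp + fp)
    rec <- safe(tp, tp + fn)
    list(accuracy = safe(tp + tn, total),
         precision = prec,
         recall = rec,
         f1 = safe(2 * tp, 2 * tp + fp + fn))
  })
  names(per) <- lv
  overall <- 100 * sum(diag(cm)) / total
  rounded <- lapply(per, function(p) lapply(p, function(v)
    if (is.na(v)) NA_real_ else round_half_up(v)))
  structure(list(matrix = cm, per_class = per,
                 overall_accuracy = overall,
                 rounded = c(rounded,
                             list(overall_accuracy = round_half_up(overall)))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted):\n")
  print(unclass(x$matrix))
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy))
  for (cls in names(x$per_class)) {
    p <- x$rounded[[cls]]
    cat(sprintf("  %-9s recall %6.2f%%  precision %6.2f%%  F1 %6.2f%%\n",
                cls, p$recall, p$precision, p$f1))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of the training protocol
#'
#' Builds a stratified fold plan over the pool, then for each round trains a
#' fresh seeded model on k-1 folds and evaluates on the held-out fold, so
#' every segment is validated exactly once. Summaries are the mean and
#' standard deviation over folds of validation accuracy, loss and anomalous
#' recall.
#'
#' @param pool a [segment_dataset()].
#' @param model_cfg a [model_config()].
#' @param cfg a [train_config()] (`cfg$k` folds, `cfg$seed` both for the fold
#'   plan and, offset per fold, for each round's model).
#' @return A list with `folds` (data frame of per-fold accuracy, loss,
#'   anomalous recall) and `summary` (mean and sd rows).
#' @export
cross_validate <- function(pool, model_cfg = model_config(),
                           cfg = train_config()) {
  stopifnot(inherits(pool, "segment_dataset"))
  plan <- make_folds(pool, k = cfg$k, seed = cfg$seed)
  rows <- vector("list", cfg$k)
  for (f in seq_len(cfg$k)) {
    hold <- plan$ids[plan$ids$fold == f, , drop = FALSE]
    keep <- plan$ids[plan$ids$fold != f, , drop = FALSE]
    i_tr <- match_manifest(pool, keep)
    i_va <- match_manifest(pool, hold)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- build_model(model_cfg, seed = fold_cfg$seed)
    fit <- train_network(model, pool$samples[i_tr, , drop = FALSE],
                         pool$label[i_tr],
                         pool$samples[i_va, , drop = FALSE],
                         pool$label[i_va], fold_cfg)
    pred <- predict_segments(fit$model,
                             pool$samples[i_va, , drop = FALSE])
    rep <- metrics(confusion(pool$label[i_va], pred$predicted))
    last <- fit$history[nrow(fit$history), ]
    rows[[f]] <- data.frame(fold = f,
                            accuracy = rep$overall_accuracy,
                            loss = last$val_loss,
                            recall_anomalous = rep$per_class$anomalous$recall)
  }
  folds <- do.call(rbind, rows)
  summ <- data.frame(
    statistic = c("mean", "sd"),
    accuracy = c(mean(folds$accuracy), stats::sd(folds$accuracy)),
    loss = c(mean(folds$loss), stats::sd(folds$loss)),
    recall_anomalous = c(mean(folds$recall_anomalous),
                         stats::sd(folds$recall_anomalous)))
  list(folds = folds, summary = summ)
}

#' Patient-level aggregation of segment predictions
#'
#' A recording (one patient) is truly anomalous iff it contains at least one
#' truly anomalous segment, and is flagged iff at least one of its segments
#' is predicted anomalous. Patient-level recall is the share of truly
#' anomalous recordings that were flagged; because one correctly detected
#' window suffices, it can only improve on segment-level recall.
#'
#' @param predictions data frame from [predict_segments()] on a
#'   `segment_dataset` (columns `record_id`, `label`, `predicted`), or any
#'   data frame with those columns.
#' @return A list with `records` (per-record truth and flag), `matrix`
#'   (patient-level `ecg_confusion`) and `recall_anomalous` (percent, `NA`
#'   when no record is truly anomalous).
#' @export
aggregate_patient_level <- function(predictions) {
  need <- c("record_id", "label", "predicted")
  if (!all(need %in% names(predictions))) {
    stop(sprintf("predictions must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  by_rec <- split(predictions, predictions$record_id)
  records <- do.call(rbind, lapply(by_rec, function(d) {
    data.frame(record_id = d$record_id[1L],
               n_segments = nrow(d),
               truth = ifelse(any(d$label == "anomalous"),
                              "anomalous", "normal"),
               flagged = ifelse(any(d$predicted == "anomalous"),
                                "anomalous", "normal"))
  }))
  rownames(records) <- NULL
  cm <- confusion(records$truth, records$flagged)
  n_true <- sum(records$truth == "anomalous")
  recall <- if (n_true == 0L) NA_real_ else
    100 * sum(records$truth == "anomalous" &
                records$flagged == "anomalous") / n_true
  list(records = records, matrix = cm, recall_anomalous = recall)
}
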