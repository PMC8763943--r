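#' Confusion counts for a binary (one-vs-rest) comparison
#'
#' @param truth True labels (factor or character).
#' @param estimate Predicted labels.
#' @param positive The positive (disease) class.
#' @return A one-row tibble with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, estimate, positive) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  stopifnot(length(truth) == length(estimate))
  tibble(
    TP = sum(truth == positive & estimate == positive),
    FP = sum(truth != positive & estimate == positive),
    TN = sum(truth != positive & estimate != positive),
    FN = sum(truth == positive & estimate != positive)
  )
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`. A zero denominator makes the corresponding metric
#' `NA` (undefined), never 0.
#'
#' @param counts A list or one-row data frame with `TP`, `FP`, `TN`, `FN`.
#' @return A one-row tibble with `accuracy`, `precision`, `recall`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (any(c(tp, fp, tn, fn) < 0)) abort("confusion counts must be non-negative")
  if (total == 0) abort("confusion counts are all zero")
  tibble(
    accuracy = (tp + tn) / total,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
}

macro_metrics <- function(truth, estimate, classes) {
  per_class <- map(classes, function(cl) {
    confusion_metrics(confusion_counts(truth, estimate, cl))
  })
  tibble(
    macro_precision = mean(map_dbl(per_class, function(x) x$precision), na.rm = TRUE),
    macro_recall = mean(map_dbl(per_class, function(x) x$recall), na.rm = TRUE)
  )
}

#' ROC curve and AUC
#'
#' Thresholds are the midpoints between consecutive distinct score values,
#' extended by sentinels below the minimum and above the maximum; a sample
#' is called positive when its score exceeds the threshold. The AUC is the
#' trapezoid-rule area under the resulting (FPR, TPR) points, which equals
#' the tie-corrected Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param truth True labels.
#' @param scores Positive-class probabilities or scores.
#' @param positive The positive class.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(truth, scores, positive) {
  truth <- as.character(truth)
  stopifnot(length(truth) == length(scores))
  is_pos <- truth == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) abort("roc_auc() needs both classes present")
  s <- sort(unique(scores))
  thr <- if (length(s) > 1) {
    c(-Inf, (head(s, -1) + tail(s, -1)) / 2, Inf)
  } else {
    c(-Inf, Inf)
  }
  pts <- map(thr, function(t) {
    call_pos <- scores > t
    tibble(
      threshold = t,
      fpr = sum(call_pos & !is_pos) / n0,
      tpr = sum(call_pos & is_pos) / n1
    )
  }) |> list_rbind()
  ord <- order(pts$fpr, pts$tpr)
  x <- pts$fpr[ord]
  y <- pts$tpr[ord]
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(roc = pts, auc = auc)
}

#' Leave-one-out cross-validation of the (multi)modal classifier
#'
#' Runs one fold per sample: the held-out sample takes no part in either
#' training stage (encoder fitting or fusion fitting), and any
#' training-dependent feature post-processing supplied through `prep` is
#' recomputed per fold from the training rows only.
#'
#' @param mats A named list of log-transformed `feature_matrix` objects
#'   (one per modality) or a single `feature_matrix`. With one modality the
#'   encoder's own softmax output is the classifier.
#' @param labels Class labels, one per sample.
#' @param seed Integer seed controlling network initialisation/batching.
#' @param configs Named list of [encoder_config()]s keyed by modality plus
#'   `fusion`; defaults to [default_model_configs()] built from `seed`.
#' @param positive Positive (disease) class; defaults to the last factor
#'   level.
#' @param prep Optional `function(train, test, modality, seed)` returning
#'   `list(train, test)`: per-fold recomputation of training-dependent
#'   feature steps (prevalence filters, reference-sample selection).
#' @param epochs,batch_size Convenience overrides used when `configs` is
#'   left at its default.
#' @param keep_models Keep each fold's fitted model (for diagnostics);
#'   off by default.
#' @return An `eval_result`: per-fold predictions, confusion counts,
#'   metrics, ROC points and AUC.
#' @export
loocv <- function(mats, labels, seed = 1L,
                  configs = default_model_configs(seed, epochs, batch_size),
                  positive = NULL, prep = NULL,
                  epochs = 100, batch_size = 16, keep_models = FALSE) {
  if (inherits(mats, "feature_matrix")) {
    mats <- setNames(list(mats), fm_modality(mats))
  }
  ids <- fm_sample_ids(mats[[1]])
  n <- length(ids)
  if (n < 3L) abort("LOOCV needs at least three samples")
  labels <- as.factor(labels)
  if (length(labels) != n) abort("labels length must equal the sample count")
  if (nlevels(droplevels(labels)) < 2L) abort("LOOCV needs at least two classes")
  labels <- droplevels(labels)
  classes <- levels(labels)
  positive <- positive %||% classes[length(classes)]
  if (!positive %in% classes) abort("positive class not among the labels")

  folds <- vector("list", n)
  models <- if (keep_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    train_lab <- labels[-i]
    fold_mats <- map(names(mats), function(mod) {
      m <- mats[[mod]]
      tr <- subset_fm(m, setdiff(seq_len(n), i))
      te <- subset_fm(m, i)
      if (!is.null(prep)) {
        pr <- prep(tr, te, mod, seed)
        tr <- pr$train
        te <- pr$test
      }
      list(train = tr, test = te)
    })
    names(fold_mats) <- names(mats)
    if (nlevels(droplevels(train_lab)) < 2L) {
      warn(sprintf(
        "fold %d: class '%s' absent from the training fold; predicting the remaining class",
        i, setdiff(classes, levels(droplevels(train_lab)))[1]
      ))
      only <- levels(droplevels(train_lab))[1]
      P <- matrix(as.numeric(classes == only), nrow = 1,
                  dimnames = list(NULL, classes))
      pred <- finish_prediction(P, ids[i], classes, "prob")
      folds[[i]] <- mutate(pred, truth = as.character(labels[i]), .after = "sample_id")
      next
    }
    if (length(fold_mats) == 1L) {
      cfg <- configs[[names(fold_mats)]] %||% configs[[1]]
      model <- train_encoder(fold_mats[[1]]$train, train_lab, cfg)
      pred <- predict(model, fold_mats[[1]]$test)
    } else {
      model <- fit_multimodal(
        map(fold_mats, function(fm) fm$train), train_lab, configs
      )
      pred <- predict(model, map(fold_mats, function(fm) fm$test))
    }
    if (keep_models) models[[i]] <- model
    folds[[i]] <- mutate(pred, truth = as.character(labels[i]), .after = "sample_id")
  }
  folds <- list_rbind(folds)
  new_eval_result(folds, classes, positive, seed, models)
}

subset_fm <- function(m, idx) {
  feature_matrix(
    as_tibble(m)[idx, , drop = FALSE],
    modality = fm_modality(m), transform = fm_transform(m)
  )
}

new_eval_result <- function(folds, classes, positive, seed, models = NULL) {
  counts <- confusion_counts(folds$truth, folds$.pred_class, positive)
  metrics <- bind_cols(
    confusion_metrics(counts),
    macro_metrics(folds$truth, folds$.pred_class, classes)
  )
  ra <- roc_auc(folds$truth, folds[[paste0(".pred_", positive)]], positive)
  structure(
    list(
      folds = folds, classes = classes, positive = positive,
      confusion = counts, metrics = metrics,
      roc = ra$roc, auc = ra$auc, seed = seed, models = models
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %d folds; accuracy %.3f, precision %.3f, recall %.3f, AUC %.3f (positive: %s)\n",
    nrow(x$folds), x$metrics$accuracy, x$metrics$precision,
    x$metrics$recall, x$auc, x$positive
  ))
  invisible(x)
}

#' Repeat LOOCV and average the metrics
#'
#' Runs `runs` independent LOOCVs under distinct seeds derived from
#' `base_seed` and averages accuracy, precision, recall and AUC; per-run
#' results are retained.
#'
#' @inheritParams loocv
#' @param runs Number of repetitions (default 5).
#' @param base_seed Seed from which per-run seeds are derived.
#' @param ... Passed on to [loocv()].
#' @return An `eval_summary`: per-run `eval_result`s, per-run metric rows
#'   and their means.
#' @export
repeat_eval <- function(mats, labels, runs = 5L, base_seed = 1L, ...) {
  stopifnot(runs >= 1L)
  run_seeds <- withr::with_seed(
    base_seed,
    sample.int(.Machine$integer.max - 1L, runs)
  )
  results <- map(run_seeds, function(s) loocv(mats, labels, seed = s, ...))
  per_run <- imap(results, function(r, i) {
    bind_cols(tibble(run = i, seed = r$seed), r$metrics, tibble(auc = r$auc))
  }) |> list_rbind()
  means <- per_run |>
    summarise(across(c(
      "accuracy", "precision", "recall",
      "macro_precision", "macro_recall", "auc"
    ), mean))
  structure(
    list(runs = results, per_run = per_run, mean_metrics = means,
         base_seed = base_seed),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> %d runs; mean accuracy %.3f, precision %.3f, recall %.3f, AUC %.3f\n",
    nrow(x$per_run), x$mean_metrics$accuracy, x$mean_metrics$precision,
    x$mean_metrics$recall, x$mean_metrics$auc
  ))
  invisible(x)
}

#' Majority-vote ensemble of classifier predictions
#'
#' Combines the per-sample predictions of several classifiers by majority
#' vote; vote ties break to the label with the highest mean predicted
#' probability, then to the first label in class order.
#'
#' @param predictions List of prediction tibbles as returned by
#'   `predict(..., type = "prob")` — each with `sample_id`, `.pred_<class>`
#'   columns and `.pred_class`.
#' @return A tibble with `sample_id` and the voted `.pred_class`.
#' @export
ensemble_vote <- function(predictions) {
  stopifnot(length(predictions) >= 2L)
  ids <- predictions[[1]]$sample_id
  for (p in predictions[-1]) {
    if (!identical(p$sample_id, ids)) abort("misaligned samples across classifiers")
  }
  classes <- levels(predictions[[1]]$.pred_class)
  votes <- map(predictions, function(p) as.character(p$.pred_class))
  prob_cols <- paste0(".pred_", classes)
  mean_probs <- Reduce(`+`, map(predictions, function(p) {
    as.matrix(p[prob_cols])
  })) / length(predictions)
  pred <- vapply(seq_along(ids), function(i) {
    tab <- table(factor(map_chr(votes, `[[`, i), levels = classes))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    mp <- mean_probs[i, paste0(".pred_", top)]
    top[order(-mp)][1]  # stable: first label wins prob ties
  }, character(1))
  tibble(sample_id = ids, .pred_class = factor(pred, levels = classes))
}
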