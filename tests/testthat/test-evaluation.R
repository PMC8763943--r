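test_that("metrics follow the confusion-count ratios", {
  m <- confusion_metrics(list(TP = 98, TN = 98, FP = 2, FN = 2))
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$precision, 0.98)
  expect_equal(m$recall, 0.98)

  perfect <- confusion_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1))

  degen <- confusion_metrics(list(TP = 0, FP = 0, TN = 3, FN = 2))
  expect_true(is.na(degen$precision))
  expect_equal(degen$recall, 0)

  expect_error(confusion_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("metrics agree with a brute-force recount on random predictions", {
  withr::with_seed(41, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      truth <- sample(c("case", "control"), n, replace = TRUE)
      est <- sample(c("case", "control"), n, replace = TRUE)
      if (!any(truth == "case")) truth[1] <- "case"
      cc <- confusion_counts(truth, est, "case")
      expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
      acc_oracle <- mean(truth == est)
      m <- confusion_metrics(cc)
      expect_identical(m$accuracy, acc_oracle)
      called <- est == "case"
      if (any(called)) {
        expect_identical(m$precision, mean(truth[called] == "case"))
      }
      expect_identical(m$recall, mean(est[truth == "case"] == "case"))
    }
  })
})

test_that("AUC equals the normalised Mann-Whitney statistic", {
  withr::with_seed(43, {
    for (i in 1:60) {
      n1 <- sample(5:25, 1)
      n0 <- sample(5:25, 1)
      scores <- c(runif(n1), runif(n0))
      if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
      truth <- rep(c("case", "control"), c(n1, n0))
      auc <- roc_auc(truth, scores, "case")$auc
      r <- rank(scores)
      u <- sum(r[truth == "case"]) - n1 * (n1 + 1) / 2
      expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
    }
  })
})

test_that("ROC endpoints, perfect ranking and score reversal behave", {
  truth <- rep(c("case", "control"), each = 4)
  perfect <- c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.3, 0.15)
  ra <- roc_auc(truth, perfect, "case")
  expect_equal(ra$auc, 1)
  expect_true(all(ra$roc$fpr >= 0 & ra$roc$fpr <= 1))
  expect_equal(max(ra$roc$tpr), 1)
  expect_equal(min(ra$roc$tpr), 0)

  withr::with_seed(47, {
    scores <- runif(30)
    truth2 <- sample(c("case", "control"), 30, replace = TRUE,
                     prob = c(0.5, 0.5))
    truth2[1:2] <- c("case", "control")
    a1 <- roc_auc(truth2, scores, "case")$auc
    a2 <- roc_auc(truth2, -scores, "case")$auc
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
  })

  expect_error(roc_auc(rep("case", 5), runif(5), "case"), "both classes")
})

test_that("AUC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    for (i in 1:10) {
      truth <- sample(c("case", "control"), 40, replace = TRUE)
      truth[1:2] <- c("case", "control")
      scores <- runif(40)
      ours <- roc_auc(truth, scores, "case")$auc
      theirs <- as.numeric(pROC::auc(
        pROC::roc(truth, scores, levels = c("control", "case"),
                  direction = "<", quiet = TRUE)
      ))
      expect_equal(ours, theirs, tolerance = 1e-12)
    }
  })
})

test_that("LOOCV produces one fold per sample and aggregates them", {
  d <- tiny_model_data(n_per_class = 5, shift = 5)
  res <- loocv(
    d$m, d$labels, seed = 3,
    configs = list(taxonomic = fast_cfg(epochs = 150)),
    positive = "case"
  )
  expect_equal(nrow(res$folds), 10L)
  expect_equal(sort(res$folds$sample_id), sort(fm_sample_ids(d$m)))
  expect_equal(sum(unlist(res$confusion)), 10)
  expect_equal(res$metrics$accuracy, 1)  # cleanly separable data
  g <- glance(res)
  expect_equal(g$n_folds, 10L)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("repeated evaluation averages runs deterministically", {
  d <- tiny_model_data(n_per_class = 4, shift = 5)
  args <- list(
    mats = d$m, labels = d$labels, runs = 2L, base_seed = 11,
    configs = list(taxonomic = fast_cfg(epochs = 20)), positive = "case"
  )
  s1 <- do.call(repeat_eval, args)
  s2 <- do.call(repeat_eval, args)
  expect_identical(s1$per_run, s2$per_run)
  expect_equal(nrow(s1$per_run), 2L)
  expect_gte(s1$mean_metrics$accuracy, min(s1$per_run$accuracy))
  expect_lte(s1$mean_metrics$accuracy, max(s1$per_run$accuracy))

  single <- loocv(d$m, d$labels, seed = s1$per_run$seed[1],
                  configs = list(taxonomic = fast_cfg(epochs = 20)),
                  positive = "case")
  expect_equal(s1$per_run$accuracy[1], single$metrics$accuracy)
})

test_that("majority voting breaks ties by mean probability", {
  mk_pred <- function(classes_chosen, p_case) {
    tibble::tibble(
      sample_id = sprintf("s%d", seq_along(classes_chosen)),
      .pred_control = 1 - p_case,
      .pred_case = p_case,
      .pred_class = factor(classes_chosen, levels = c("control", "case"))
    )
  }
  votes <- list(
    mk_pred(c("case", "case"), c(0.9, 0.6)),
    mk_pred(c("case", "control"), c(0.8, 0.2)),
    mk_pred(c("control", "control"), c(0.4, 0.3))
  )
  out <- ensemble_vote(votes)
  expect_equal(as.character(out$.pred_class), c("case", "control"))

  # two classifiers, split vote: mean probability decides
  tie <- list(
    mk_pred("case", 0.9),
    mk_pred("control", 0.5)
  )
  expect_equal(as.character(ensemble_vote(tie)$.pred_class), "case")

  unanimous <- list(mk_pred("control", 0.1), mk_pred("control", 0.2))
  expect_equal(as.character(ensemble_vote(unanimous)$.pred_class), "control")

  misaligned <- list(
    mk_pred(c("case", "case"), c(0.9, 0.8)),
    dplyr::arrange(mk_pred(c("case", "case"), c(0.9, 0.8)),
                   dplyr::desc(sample_id))
  )
  expect_error(ensemble_vote(misaligned), "misaligned")
})
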