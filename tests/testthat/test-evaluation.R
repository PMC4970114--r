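test_that("LOSO folds hold out each subject exactly once", {
  subs <- sprintf("S%02d", 1:10)
  folds <- loso_folds(rep(subs, each = 5))
  expect_length(folds, 10)
  expect_setequal(vapply(folds, `[[`, "", "test"), subs)
  for (f in folds) {
    expect_length(f$train, 9)
    expect_false(f$test %in% f$train)
  }
  expect_length(loso_folds(c("A", "B")), 2)
  expect_error(loso_folds("A"), "at least 2")
})

test_that("confusion matrices count true/predicted pairs with conservation", {
  counts <- c(322, 1155, 271, 437)
  truth <- rep(1:4, counts)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm)), counts)
  expect_equal(sum(cm), sum(counts))
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
  expect_error(confusion_matrix(c(1, 5), c(1, 1)), "1-4")

  set.seed(55)
  true <- sample(1:4, 300, replace = TRUE)
  pred <- sample(1:4, 300, replace = TRUE)
  cm <- confusion_matrix(true, pred)
  expect_equal(sum(cm), 300)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(true, 1:4)))))
})

test_that("per-class metrics agree with a direct counting oracle on random labelings", {
  set.seed(77)
  for (i in 1:20) {
    true <- sample(1:4, 200, replace = TRUE)
    pred <- sample(1:4, 200, replace = TRUE)
    mets <- metrics_from_confusion(confusion_matrix(true, pred))
    for (k in 1:4) {
      tp <- sum(true == k & pred == k)
      fp <- sum(true != k & pred == k)
      fn <- sum(true == k & pred != k)
      expect_equal(mets$per_class$tp[k], tp)
      expect_equal(mets$per_class$fp[k], fp)
      expect_equal(mets$per_class$fn[k], fn)
      p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
      r <- 100 * tp / (tp + fn)
      expect_equal(mets$per_class$precision[k], p, tolerance = 1e-12)
      expect_equal(mets$per_class$recall[k], r, tolerance = 1e-12)
    }
    expect_equal(mets$macro$f1, mean(mets$per_class$f1), tolerance = 1e-9)
    expect_equal(mets$macro$precision, mean(mets$per_class$precision),
                 tolerance = 1e-9)
  }
})

test_that("identity confusion matrix gives 100% everywhere; absent class errors", {
  cm <- diag(c(5L, 6L, 7L, 8L))
  mets <- metrics_from_confusion(cm)
  expect_equal(mets$per_class$f1, rep(100, 4))
  expect_equal(mets$macro$f1, 100)
  cm[2, ] <- 0L
  expect_error(metrics_from_confusion(cm), "at least one true instance")
})

test_that("F1 is the harmonic mean of precision and recall with 0/0 -> 0", {
  expect_equal(round_half_up(f1_from_pr(96.58, 96.58)), 96.58)
  expect_equal(round_half_up(f1_from_pr(93.14, 95.20)), 94.16)
  expect_equal(f1_from_pr(0, 0), 0)
  for (p in c(1, 37.5, 80, 100)) expect_equal(f1_from_pr(p, p), p)
  expect_lte(f1_from_pr(60, 90), 90)
  expect_gte(f1_from_pr(60, 90), 60)
})

test_that("ROC/AUC: perfect ranking gives 1, uninformative scores give 0.5", {
  labels <- c(rep(1, 10), rep(0, 10))
  expect_equal(roc_auc(labels, seq(20, 1))$auc, 1)
  expect_equal(roc_auc(labels, rep(3.7, 20))$auc, 0.5)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
  expect_error(roc_auc(labels, c(Inf, rnorm(19))), "finite")
})

test_that("trapezoidal AUC equals the pair-counting statistic, incl. tied scores", {
  toy_labels <- c(1, 1, 0, 1, 0, 0)
  toy_scores <- c(0.9, 0.7, 0.7, 0.5, 0.4, 0.1)
  expect_equal(roc_auc(toy_labels, toy_scores)$auc,
               oracle_auc(toy_labels, toy_scores))
  set.seed(88)
  for (i in 1:30) {
    n <- sample(10:100, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    expect_equal(roc_auc(labels, scores)$auc, oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("threshold-sweep AUC matches an independent ROC implementation", {
  set.seed(99)
  labels <- sample(0:1, 80, replace = TRUE, prob = c(0.6, 0.4))
  scores <- rnorm(80) + labels
  ours <- roc_auc(labels, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the LOSO experiment report is internally consistent", {
  feats <- small_cohort_features()
  rep2 <- cached("small_report_two_stage", run_experiment(feats, "two_stage"))
  expect_s3_class(rep2, "evaluation_report")
  expect_equal(sum(rep2$confusion), nrow(feats))         # conservation
  expect_equal(rep2$n_epochs, nrow(feats))
  expect_equal(nrow(rep2$fold_macro), 4)
  expect_equal(rep2$macro$f1, mean(rep2$per_class$f1), tolerance = 1e-9)
  aucs <- unlist(rep2$auc[class_levels()])
  expect_true(all(aucs >= 0 & aucs <= 1))
  expect_equal(rep2$auc$mean, mean(aucs), tolerance = 1e-12)
  # row sums = true class counts
  expect_equal(unname(rowSums(rep2$confusion)),
               unname(as.vector(table(factor(feats$label, 1:4)))))
})

test_that("the two-stage table fixture is exactly self-consistent under pooling", {
  fx <- load_confusion_fixture("table4")
  mets <- metrics_from_confusion(fx$confusion)
  expect_equal(round_half_up(mets$per_class$precision), fx$printed$precision)
  expect_equal(round_half_up(mets$per_class$recall), fx$printed$recall)
  expect_equal(round_half_up(mets$per_class$f1), fx$printed$f1)
  expect_equal(sum(fx$confusion), 2185)
})

test_that("reports survive JSON serialization", {
  feats <- small_cohort_features()
  rep2 <- cached("small_report_two_stage", run_experiment(feats, "two_stage"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep2, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$macro$f1, rep2$macro$f1, tolerance = 1e-12)
  expect_equal(back$n_epochs, rep2$n_epochs)
})
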