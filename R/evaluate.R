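#' Leave-one-subject-out folds
#'
#' One fold per subject: all of that subject's epochs form the validation
#' set, the remaining subjects form the training set. This tests
#' subject-independent generalization.
#'
#' @param subjects character vector of per-epoch subject ids (or the unique
#'   ids themselves).
#' @return list of folds, each a list with `train` (ids) and `test` (one id).
#' @export
loso_folds <- function(subjects) {
  ids <- unique(as.character(subjects))
  if (length(ids) < 2L) {
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  }
  lapply(ids, function(s) list(train = setdiff(ids, s), test = s))
}

#' Confusion matrix over the four activity classes
#'
#' @param true,predicted integer class codes 1-4 of equal length.
#' @return 4 x 4 integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted, both ordered eat_sit, sedentary, eat_walk,
#'   walk.
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(true) != length(predicted)) {
    stop("'true' and 'predicted' must have equal length", call. = FALSE)
  }
  if (!all(true %in% 1:4) || !all(predicted %in% 1:4)) {
    stop("labels must be class codes 1-4", call. = FALSE)
  }
  tf <- factor(true, levels = 1:4, labels = class_names())
  pf <- factor(predicted, levels = 1:4, labels = class_names())
  cm <- unclass(table(true = tf, predicted = pf))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' F1-score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`, on the percentage scale. The
#' degenerate case P = R = 0 is defined as 0.
#'
#' @param precision,recall percentages in \[0, 100\].
#' @return F1 as a percentage (unrounded).
#' @export
f1_from_pr <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class and macro metrics from a confusion matrix
#'
#' For class k: TP is the diagonal cell, FN the rest of row k, FP the rest of
#' column k; precision = TP/(TP+FP), recall = TP/(TP+FN) (percentages, 0/0
#' defined as 0), F1 their harmonic mean. Macro values are unweighted
#' arithmetic means over the four classes, computed before any rounding.
#'
#' @param cm a [confusion_matrix()] (any 4 x 4 count matrix works).
#' @return list with `per_class` (data.frame: class, tp, fp, fn, precision,
#'   recall, f1) and `macro` (precision, recall, f1), all percentages,
#'   unrounded.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == 4, ncol(cm) == 4, all(cm >= 0))
  if (any(rowSums(cm) == 0)) {
    stop("every class must have at least one true instance", call. = FALSE)
  }
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, 100 * tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, 100 * tp / (tp + fn))
  f1 <- f1_from_pr(precision, recall)
  list(
    per_class = data.frame(class = class_names(), tp = as.integer(tp),
                           fp = as.integer(fp), fn = as.integer(fn),
                           precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1),
                           row.names = NULL, stringsAsFactors = FALSE),
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1))
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all distinct score values as decision thresholds (predict positive
#' when score >= threshold) and integrates the resulting TPR-vs-FPR curve by
#' the trapezoidal rule. Tied scores are handled by grouping, which makes the
#' trapezoidal area equal the Mann-Whitney rank statistic
#' P(score+ > score-) + 0.5 P(score+ = score-).
#'
#' @param labels binary labels: 1/TRUE for positives, 0/FALSE/-1 for
#'   negatives; both classes must be present.
#' @param scores finite numeric scores, higher = more positive.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`,
#'   including the (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- labels %in% c(1, TRUE)
  neg <- !pos
  if (!any(pos) || !any(neg)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores: one operating point per distinct threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(p)[last_of_group]
  cum_fp <- cumsum(!p)[last_of_group]
  tpr <- c(0, cum_tp / sum(pos))
  fpr <- c(0, cum_fp / sum(neg))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, s[last_of_group]),
                           fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Run the full leave-one-subject-out experiment
#'
#' For each fold, trains the requested architecture on the training subjects'
#' epochs and predicts the held-out subject's epochs. Validation predictions
#' and scores from all folds are pooled into one confusion matrix, per-class
#' and macro precision/recall/F1, and pooled one-vs-rest ROC/AUC per class.
#' Per-fold macro metrics are also reported, since averaging over folds is
#' the other common aggregation.
#'
#' @param features cohort feature table from [featurize_cohort()].
#' @param arch `"two_stage"` or `"single"` (one-vs-all multiclass).
#' @param C soft-margin regularization constant passed to the SVMs.
#' @return a list of class `evaluation_report`: `arch`, `confusion`,
#'   `per_class`, `macro`, `fold_macro` (means over folds), `auc` (per class
#'   + mean), `roc` (per-class ROC points), `folds` manifest, `n_epochs`.
#' @export
run_experiment <- function(features, arch = c("two_stage", "single"),
                           C = 1.0) {
  arch <- match.arg(arch)
  chew_cols <- feature_columns()[1:4]
  acc_cols <- feature_columns()[5:8]
  folds <- loso_folds(features$subject)
  true_all <- integer(0)
  pred_all <- integer(0)
  scores_all <- NULL
  fold_of <- character(0)
  fold_macro <- data.frame()
  for (fold in folds) {
    tr <- features[features$subject %in% fold$train, , drop = FALSE]
    te <- features[features$subject == fold$test, , drop = FALSE]
    if (arch == "single") {
      model <- train_multiclass_ova(as.matrix(tr[, feature_columns()]),
                                    tr$label, C = C)
      pr <- predict(model, as.matrix(te[, feature_columns()]))
    } else {
      model <- train_two_stage(as.matrix(tr[, chew_cols]),
                               as.matrix(tr[, acc_cols]), tr$label, C = C)
      pr <- predict_two_stage(model, as.matrix(te[, chew_cols]),
                              as.matrix(te[, acc_cols]))
    }
    true_all <- c(true_all, te$label)
    pred_all <- c(pred_all, pr$class)
    scores_all <- rbind(scores_all, pr$scores)
    fold_of <- c(fold_of, rep(fold$test, nrow(te)))
    fm <- metrics_from_confusion(confusion_matrix(te$label, pr$class))$macro
    fold_macro <- rbind(fold_macro,
                        data.frame(test_subject = fold$test,
                                   precision = fm$precision,
                                   recall = fm$recall, f1 = fm$f1))
  }
  cm <- confusion_matrix(true_all, pred_all)
  mets <- metrics_from_confusion(cm)
  roc <- lapply(1:4, function(k) {
    roc_auc(as.integer(true_all == k), scores_all[, k])
  })
  names(roc) <- class_names()
  auc <- vapply(roc, function(r) r$auc, numeric(1))
  structure(
    list(arch = arch, C = C, confusion = cm,
         per_class = mets$per_class, macro = mets$macro,
         fold_macro = fold_macro,
         auc = c(as.list(auc), list(mean = mean(auc))),
         roc = lapply(roc, function(r) r$points),
         folds = data.frame(test_subject = vapply(folds, `[[`, "",
                                                  "test")),
         n_epochs = length(true_all)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s architecture, %d pooled validation epochs, %d LOSO folds\n",
              x$arch, x$n_epochs, nrow(x$folds)))
  tab <- cbind(as.data.frame(unclass(x$confusion)),
               recall = sprintf("%.2f%%", round_half_up(x$per_class$recall)),
               f1 = sprintf("%.2f%%", round_half_up(x$per_class$f1)))
  print(tab)
  cat("precision:",
      paste(sprintf("%.2f%%", round_half_up(x$per_class$precision)),
            collapse = "  "), "\n")
  cat(sprintf("macro  P %.2f%%  R %.2f%%  F1 %.2f%%   mean AUC %.3f\n",
              round_half_up(x$macro$precision), round_half_up(x$macro$recall),
              round_half_up(x$macro$f1), x$auc$mean))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    arch = report$arch, C = report$C,
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    macro = report$macro,
    fold_macro = report$fold_macro,
    auc = report$auc,
    n_epochs = report$n_epochs
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
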