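#' Train a binary linear SVM
#'
#' Fits a soft-margin linear support-vector machine (hinge loss + L2 penalty,
#' solved by libsvm via \pkg{e1071}) on z-scored features. The
#' standardization statistics are computed from the training rows only and
#' stored in the model, so no information leaks from validation subjects. The
#' decision score is `s(x) = w . standardize(x) + b`, with `s >= 0` read as
#' the positive class.
#'
#' @param x numeric matrix (rows = epochs, columns = features).
#' @param y labels in \{-1, +1\}, one per row; both classes must be present.
#' @param C soft-margin regularization constant (default 1).
#' @return a list of class `linear_model`: `weights`, `bias`, `center`,
#'   `scale`, `C`.
#' @export
train_binary <- function(x, y, C = 1.0) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("rows of 'x' must match 'y'", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("'x' contains missing or non-finite values", call. = FALSE)
  }
  if (!all(y %in% c(-1, 1))) stop("'y' must be -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in 'y'", call. = FALSE)
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1  # constant feature: leave centred values at zero
  xs <- scale(x, center = ctr, scale = scl)
  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the first label it encounters
  if (fit$levels[fit$labels[1]] == "-1") {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b, center = ctr, scale = scl, C = C),
            class = "linear_model")
}

#' Decision scores of a linear model
#'
#' @param object a `linear_model` from [train_binary()].
#' @param x numeric matrix with the same columns as the training features.
#' @param ... unused.
#' @return numeric vector of signed decision scores.
#' @export
predict.linear_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != length(object$weights)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  xs <- scale(x, center = object$center, scale = object$scale)
  as.numeric(xs %*% object$weights + object$bias)
}

#' Train the single one-vs-all multiclass linear SVM
#'
#' One binary linear SVM per activity class (that class against the rest) on
#' the fused 8-feature vector. Prediction takes the class with the maximal
#' decision score; arg-max ties break toward the lowest class code.
#'
#' @param x numeric matrix of fused features (8 columns).
#' @param labels integer class codes 1-4 (see [class_levels()]); all four
#'   classes must be present in the training fold.
#' @param C soft-margin regularization constant.
#' @return a list of class `ova_model`: four `linear_model`s, one per class.
#' @export
train_multiclass_ova <- function(x, labels, C = 1.0) {
  labels <- as.integer(labels)
  present <- sort(unique(labels))
  if (!all(1:4 %in% present)) {
    stop("all four classes must be present in the training fold; missing: ",
         paste(setdiff(1:4, present), collapse = ", "), call. = FALSE)
  }
  models <- lapply(1:4, function(k) {
    train_binary(x, ifelse(labels == k, 1, -1), C = C)
  })
  names(models) <- class_names()
  structure(list(models = models, C = C), class = "ova_model")
}

#' @export
print.ova_model <- function(x, ...) {
  cat("<ova_model> one-vs-all linear SVM, 4 classes, C =", x$C, "\n")
  invisible(x)
}

#' Predict with the one-vs-all model
#'
#' @param object an `ova_model`.
#' @param x fused feature matrix.
#' @param ... unused.
#' @return list with `class` (integer codes, arg-max of the per-class scores,
#'   ties to the lowest code) and `scores` (n x 4 matrix of decision scores).
#' @export
predict.ova_model <- function(object, x, ...) {
  scores <- vapply(object$models, predict, numeric(nrow(as.matrix(x))),
                   x = x)
  scores <- matrix(scores, ncol = 4,
                   dimnames = list(NULL, class_names()))
  list(class = max.col(scores, ties.method = "first"), scores = scores)
}

# Decision rules fusing the two binary stage outputs into the final class:
#   intake & no-walking -> eating while sitting (1)
#   no-intake & no-walking -> sedentary (2)
#   intake & walking -> eating while walking (3)
#   no-intake & walking -> walking (4)
fusion_table <- function() {
  data.frame(c_chew = c(1, -1, 1, -1),
             c_acc = c(-1, -1, 1, 1),
             class = 1:4)
}

#' Fuse the two stage outputs into the final class
#'
#' @param c_chew intake-detector output: -1 (no food intake) or +1 (intake).
#' @param c_acc activity-detector output: -1 (no walking) or +1 (walking).
#' @return integer class code(s): see [fusion_table] rules above.
#' @export
fuse <- function(c_chew, c_acc) {
  if (!all(c_chew %in% c(-1, 1)) || !all(c_acc %in% c(-1, 1))) {
    stop("stage outputs must be -1 or +1", call. = FALSE)
  }
  # enumerate the four (c_chew, c_acc) combinations
  ifelse(c_chew == 1,
         ifelse(c_acc == 1, 3L, 1L),
         ifelse(c_acc == 1, 4L, 2L))
}

#' Train the two-stage classifier
#'
#' Stage one trains two independent binary linear SVMs: a food-intake
#' detector on the four piezoelectric features (intake = eating classes 1 and
#' 3) and a walking detector on the four accelerometer features (walking =
#' classes 3 and 4). Stage two maps the two signed outputs to the final class
#' with [fuse()].
#'
#' @param x_chew piezoelectric feature matrix (4 columns).
#' @param x_acc accelerometer feature matrix (4 columns).
#' @param labels integer class codes 1-4.
#' @param C soft-margin regularization constant.
#' @return a list of class `two_stage_model` with `chew_model` and
#'   `activity_model`.
#' @export
train_two_stage <- function(x_chew, x_acc, labels, C = 1.0) {
  labels <- as.integer(labels)
  y_chew <- ifelse(labels %in% c(1L, 3L), 1, -1)
  y_acc <- ifelse(labels %in% c(3L, 4L), 1, -1)
  structure(
    list(chew_model = train_binary(x_chew, y_chew, C = C),
         activity_model = train_binary(x_acc, y_acc, C = C),
         C = C),
    class = "two_stage_model"
  )
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat("<two_stage_model> intake SVM (piezo) + walking SVM (accel) + decision rules, C =",
      x$C, "\n")
  invisible(x)
}

#' Predict with the two-stage classifier
#'
#' Hard labels come from the signs of the two stage scores (a score of
#' exactly zero counts as +1) fused through the decision rules. For ROC
#' analysis each class also gets a continuous score: the minimum of the two
#' stage scores oriented toward that class's rule combination, which is
#' monotone in both stages and reduces to a single stage's score when the
#' other stage is confident.
#'
#' @param model a `two_stage_model`.
#' @param x_chew piezoelectric feature matrix.
#' @param x_acc accelerometer feature matrix.
#' @return list with `class` (integer codes), `scores` (n x 4 oriented
#'   per-class scores), and the raw stage scores `s_chew`, `s_acc`.
#' @export
predict_two_stage <- function(model, x_chew, x_acc) {
  s_chew <- predict(model$chew_model, x_chew)
  s_acc <- predict(model$activity_model, x_acc)
  sgn <- function(s) ifelse(s >= 0, 1, -1)  # sign(0) -> +1 by convention
  cls <- fuse(sgn(s_chew), sgn(s_acc))
  tab <- fusion_table()
  scores <- sapply(1:4, function(k) {
    pmin(tab$c_chew[k] * s_chew, tab$c_acc[k] * s_acc)
  })
  scores <- matrix(scores, ncol = 4, dimnames = list(NULL, class_names()))
  list(class = cls, scores = scores, s_chew = s_chew, s_acc = s_acc)
}
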