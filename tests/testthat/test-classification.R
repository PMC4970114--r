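make_lm <- function(weights, bias = 0) {
  structure(list(weights = weights, bias = bias,
                 center = rep(0, length(weights)),
                 scale = rep(1, length(weights)), C = 1),
            class = "linear_model")
}

test_that("a binary linear SVM separates well-separated clouds perfectly", {
  set.seed(21)
  x <- matrix(c(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1)), ncol = 1)
  y <- c(rep(-1, 50), rep(1, 50))
  m <- train_binary(x, y)
  expect_equal(ifelse(predict(m, x) >= 0, 1, -1), y)
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(train_binary(x, rep(1, 10)), "both classes")
  expect_error(train_binary(x, c(rep(1, 5), rep(2, 5))), "-1/\\+1")
  x[3, 1] <- NaN
  expect_error(train_binary(x, c(rep(1, 5), rep(-1, 5))), "non-finite")
})

test_that("mirror-symmetric data yields a (near) zero bias after standardization", {
  v <- seq(0.5, 2, by = 0.1)
  x <- matrix(c(v, -v), ncol = 1)
  y <- c(rep(1, length(v)), rep(-1, length(v)))
  m <- train_binary(x, y)
  expect_lt(abs(m$bias), 1e-6)
})

test_that("retraining on identical data reproduces identical predictions", {
  feats <- small_cohort_features()
  x <- as.matrix(feats[, feature_columns()[1:4]])
  y <- ifelse(feats$label %in% c(1, 3), 1, -1)
  m1 <- train_binary(x, y)
  m2 <- train_binary(x, y)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("decision rules map stage outputs to classes exactly and bijectively", {
  expect_identical(fuse(1, -1), 1L)   # intake, not walking
  expect_identical(fuse(-1, -1), 2L)  # sedentary
  expect_identical(fuse(1, 1), 3L)    # eating while walking
  expect_identical(fuse(-1, 1), 4L)   # walking
  combos <- expand.grid(c_chew = c(-1, 1), c_acc = c(-1, 1))
  expect_setequal(fuse(combos$c_chew, combos$c_acc), 1:4)
  expect_error(fuse(0, 1), "-1 or \\+1")
})

test_that("two-stage prediction follows the sign rule with sign(0) -> +1", {
  model <- structure(list(chew_model = make_lm(1), activity_model = make_lm(1),
                          C = 1),
                     class = "two_stage_model")
  pr <- predict_two_stage(model, matrix(2), matrix(-3))
  expect_equal(pr$class, 1L)  # s_chew = +2, s_acc = -3 -> eating while sitting
  expect_equal(unname(pr$scores[1, "eat_walk"]), min(2, -3))
  pr0 <- predict_two_stage(model, matrix(0), matrix(-1))
  expect_equal(pr0$class, 1L)  # zero chew score counts as intake
  pr4 <- predict_two_stage(model, matrix(-2), matrix(5))
  expect_equal(pr4$class, 4L)
  expect_equal(unname(pr4$scores[1, "walk"]), min(2, 5))
})

test_that("hard two-stage labels are invariant to monotone score rescaling", {
  feats <- small_cohort_features()
  xc <- as.matrix(feats[, feature_columns()[1:4]])
  xa <- as.matrix(feats[, feature_columns()[5:8]])
  m <- train_two_stage(xc, xa, feats$label)
  base <- predict_two_stage(m, xc, xa)
  scaled <- m
  scaled$chew_model$weights <- 7 * scaled$chew_model$weights
  scaled$chew_model$bias <- 7 * scaled$chew_model$bias
  scaled$activity_model$weights <- 0.01 * scaled$activity_model$weights
  scaled$activity_model$bias <- 0.01 * scaled$activity_model$bias
  expect_identical(predict_two_stage(scaled, xc, xa)$class, base$class)
})

test_that("one-vs-all model predicts by arg-max with ties to the lowest code", {
  set.seed(31)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  x <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(60, 0, 0.2), ncol = 2), 2, centers[k, ], `+`)
  }))
  labels <- rep(1:4, each = 30)
  m <- train_multiclass_ova(x, labels)
  expect_equal(predict(m, x)$class, labels)

  lm0 <- make_lm(c(1, 0))
  tie <- structure(list(models = list(lm0, lm0, lm0, lm0), C = 1),
                   class = "ova_model")
  expect_equal(predict(tie, matrix(c(2, 0), ncol = 2))$class, 1L)
})

test_that("one-vs-all training requires all four classes", {
  feats <- small_cohort_features()
  sub <- feats[feats$label != 3, ]
  expect_error(train_multiclass_ova(as.matrix(sub[, feature_columns()]),
                                    sub$label), "missing")
})

test_that("both architectures reach zero training error on a separable cohort", {
  feats <- small_cohort_features()
  x <- as.matrix(feats[, feature_columns()])
  ova <- train_multiclass_ova(x, feats$label)
  acc_single <- mean(predict(ova, x)$class == feats$label)
  two <- train_two_stage(x[, 1:4], x[, 5:8], feats$label)
  acc_two <- mean(predict_two_stage(two, x[, 1:4], x[, 5:8])$class ==
                    feats$label)
  # "separable" up to epochs that fall inside chewing pauses; require near-perfect
  expect_gte(acc_single, 0.97)
  expect_gte(acc_two, 0.97)
})

test_that("models survive a JSON round trip with identical predictions", {
  feats <- small_cohort_features()
  x <- as.matrix(feats[, feature_columns()])
  tmp <- withr::local_tempfile(fileext = ".json")
  ova <- train_multiclass_ova(x, feats$label)
  write_model(ova, tmp)
  expect_equal(predict(read_model(tmp), x)$scores, predict(ova, x)$scores,
               tolerance = 1e-12)
  two <- train_two_stage(x[, 1:4], x[, 5:8], feats$label)
  write_model(two, tmp)
  back <- read_model(tmp)
  expect_identical(predict_two_stage(back, x[, 1:4], x[, 5:8])$class,
                   predict_two_stage(two, x[, 1:4], x[, 5:8])$class)
})
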