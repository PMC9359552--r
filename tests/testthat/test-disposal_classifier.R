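# Separable three-class toy features used in several blocks.
toy_data <- function(n_per_class, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(rnorm(n_per_class, -6, 0.5), rnorm(n_per_class, 0, 0.5)),
      cbind(rnorm(n_per_class, 0, 0.5), rnorm(n_per_class, 6, 0.5)),
      cbind(rnorm(n_per_class, 6, 0.5), rnorm(n_per_class, 0, 0.5))
    )
    y <- factor(rep(c("high", "nearby", "low"), each = n_per_class),
      levels = c("high", "nearby", "low")
    )
    list(x = data.frame(f1 = x[, 1], f2 = x[, 2]), y = y)
  })
}

test_that("stratified split preserves class shares under the floor rule", {
  d <- toy_data(334) # 1002 samples
  cfg <- rf_config(seed = 4)
  sp <- split_data(d$x, d$y, cfg)
  expect_equal(length(sp$train), floor(0.8 * 1002))
  tr_counts <- table(d$y[sp$train])
  expect_true(all(abs(tr_counts - floor(0.8 * 334)) <= 1))
  expect_equal(sort(c(sp$train, sp$test)), seq_along(d$y))
  # same seed, same split
  sp2 <- split_data(d$x, d$y, cfg)
  expect_identical(sp, sp2)

  # the 1943-sample convention: 1554 train / 389 test
  y3 <- factor(rep(c("high", "nearby", "low"), times = c(648, 648, 647)),
    levels = c("high", "nearby", "low")
  )
  x3 <- data.frame(f = seq_along(y3))
  sp3 <- split_data(x3, y3, rf_config(seed = 1))
  expect_equal(length(sp3$train), 1554)
  expect_equal(length(sp3$test), 389)

  expect_error(
    split_data(d$x[1:20, ], factor(rep("high", 20), levels = levels(d$y))),
    "class absent"
  )
})

test_that("training is reproducible and order-invariant over feature columns", {
  d <- toy_data(60)
  cfg <- rf_config(seed = 5, min_split = 5, min_leaf = 2)
  m1 <- train_rf(d$x, d$y, cfg)
  m2 <- train_rf(d$x, d$y, cfg)
  expect_identical(predict_class(m1, d$x), predict_class(m2, d$x))
  # separable data: perfect training accuracy
  expect_equal(mean(predict_class(m1, d$x) == d$y), 1.0)
  # permuted (named) columns give identical predictions
  expect_identical(
    predict_class(m1, d$x[, c("f2", "f1")]),
    predict_class(m1, d$x)
  )
  expect_error(train_rf(d$x[1:60, ], droplevels(d$y[1:60])), "one class")
})

test_that("precision, recall and F1 match hand-computed values", {
  cm <- matrix(
    c(
      50, 0, 0,
      0, 0, 50,
      0, 0, 50
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("H", "N", "L"), c("H", "N", "L"))
  )
  m <- precision_recall_f1(cm)
  expect_equal(m$precision[m$class == "L"], 0.5)
  expect_equal(m$recall[m$class == "N"], 0)
  expect_equal(m$precision[m$class == "H"], 1)
  expect_equal(m$recall[m$class == "H"], 1)
  expect_equal(m$f1[m$class == "H"], 1)
  expect_equal(m$f1[m$class == "N"], 0)

  truth <- c("a", "a", "b", "b")
  pred <- c("a", "b", "b", "b")
  cm2 <- confusion_matrix(truth, pred)
  expect_equal(unname(rowSums(cm2)), c(2, 2)) # row sums = true class counts
  expect_equal(macro_f1(truth, truth), 1.0)
})

test_that("ROC and PR areas agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (k in 1:5) {
    y <- c(rep(TRUE, 40), rep(FALSE, 60))
    s <- ifelse(y, rnorm(100, 1), rnorm(100)) # overlapping scores
    ours <- roc_auc(y, s)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # perfect and chance-level behaviour
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1)), 1.0)
  set.seed(16)
  y <- rep(c(TRUE, FALSE), 1500)
  expect_equal(roc_auc(y, runif(3000)), 0.5, tolerance = 0.05)
  expect_equal(pr_auc(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1)), 1.0)
})

test_that("evaluation reports are complete and consistent", {
  d <- toy_data(120, seed = 3)
  cfg <- rf_config(seed = 6, min_split = 10, min_leaf = 2)
  sp <- split_data(d$x, d$y, cfg)
  m <- train_rf(d$x[sp$train, ], d$y[sp$train], cfg)
  rep <- evaluate_model(m, d$x[sp$test, ], d$y[sp$test])
  expect_s3_class(rep, "eval_report")
  # separable: everything perfect
  expect_equal(rep$per_class$precision, rep(1, 3))
  expect_equal(rep$per_class$recall, rep(1, 3))
  expect_equal(rep$per_class$roc_auc, rep(1, 3))
  expect_equal(rep$per_class$pr_auc, rep(1, 3))
  expect_equal(rep$roc_auc_micro, 1.0)
  expect_equal(unname(diag(rep$confusion)), as.integer(table(d$y[sp$test])[m$levels]))
  # confusion row sums equal test-class counts
  expect_equal(
    as.integer(rowSums(rep$confusion)),
    as.integer(table(d$y[sp$test])[m$levels])
  )
  # importances normalised
  expect_equal(sum(rep$importance), 1, tolerance = 1e-9)
  # vote fractions are proper scores
  v <- predict_votes(m, d$x[sp$test, ])
  expect_equal(unname(rowSums(v)), rep(1, length(sp$test)), tolerance = 1e-9)
})

test_that("feature elimination removes a planted noise column first", {
  d <- simulate_elimination_data(900, n_informative = 4, seed = 17)
  cfg <- rf_config(seed = 17, n_trees = 300, min_split = 10, min_leaf = 2)
  kept <- eliminate_features(d$x, d$y, cfg)
  tr <- attr(kept, "trace")
  expect_equal(tr$dropped[2], "NOISE") # first removal is the noise column
  expect_setequal(kept, sprintf("F%d", 1:4)) # informative set retained
})
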