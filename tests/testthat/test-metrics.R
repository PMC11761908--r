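folds_real <- function() {
  read_fold_table(system.file("extdata", "benchmark_folds_real.csv",
                              package = "lwunet"))
}
folds_aug <- function() {
  read_fold_table(system.file("extdata", "benchmark_folds_augmented.csv",
                              package = "lwunet"))
}

test_that("confusion matrices count exactly", {
  y <- c("benign", "benign", "malignant", "malignant")
  cm <- confusion_matrix(y, y)
  expect_equal(as.integer(cm), c(2L, 0L, 0L, 2L))
  # a 76% benign recall on a 1300-per-class test set gives row (988, 312)
  truth <- rep(c("benign", "malignant"), each = 1300)
  pred <- c(rep("benign", 988), rep("malignant", 312),
            rep("malignant", 1300))
  cm <- confusion_matrix(truth, pred)
  expect_equal(unname(cm["benign", ]), c(988L, 312L))
  expect_equal(unname(rowSums(cm)), c(1300, 1300))
  expect_error(confusion_matrix(c("benign", "cyst"), c("benign", "benign")),
               class = "lwunet_input_error")
})

test_that("per-class metrics follow the one-vs-rest formulas in percent", {
  cm <- confusion_matrix(c(rep("benign", 10), rep("malignant", 10)),
                         c(rep("benign", 8), rep("malignant", 2),
                           rep("malignant", 8), rep("benign", 2)))
  m <- class_metrics(cm)
  expect_equal(m$per_class$precision[1], 80)
  expect_equal(m$accuracy, 80)
  # TP = TN = FP = FN > 0 gives 50% accuracy
  cm2 <- confusion_matrix(rep(c("benign", "malignant"), each = 2),
                          c("benign", "malignant", "benign", "malignant"))
  expect_equal(class_metrics(cm2)$accuracy, 50)
  # published precision/recall pair reproduces its published F1
  f1 <- 2 * 86.898 * 86.667 / (86.898 + 86.667)
  expect_equal(round(f1, 3), 86.782)
  # 0/0 convention: zero denominator reported as 0 with a warning
  cm3 <- confusion_matrix(rep("benign", 3), rep("benign", 3))
  expect_warning(m3 <- class_metrics(cm3), "zero denominator")
  expect_equal(m3$per_class$precision[2], 0)
})

test_that("macro and weighted averages follow their definitions", {
  expect_equal(average_metrics(c(100, 0), c(3, 1), "weighted"), 75)
  expect_equal(average_metrics(c(100, 0), c(3, 1), "macro"), 50)
  expect_equal(average_metrics(c(80, 90), c(5, 5), "macro"),
               average_metrics(c(80, 90), c(5, 5), "weighted"))
  expect_equal(average_metrics(42, 7, "macro"), 42)
  expect_equal(average_metrics(42, 7, "weighted"), 42)
  expect_error(average_metrics(c(1, 2), c(0, 0)), class = "lwunet_input_error")
})

test_that("fold aggregation reproduces published Average/Overall rows", {
  agg <- aggregate_folds(folds_real())
  expect_equal(round(agg$accuracy, 3), 86.867)
  expect_equal(round(agg$per_class$benign$precision, 4), 88.4652)
  expect_equal(round(agg$per_class$benign$recall, 3), 84.960)
  expect_equal(round(agg$per_class$benign$f1, 3), 86.521)
  expect_equal(round(agg$per_class$malignant$precision, 4), 85.8488)
  expect_equal(round(agg$overall$precision, 3), 87.157)
  expect_equal(round(agg$overall$recall, 4), 86.8666)
  expect_equal(round(agg$overall$f1, 4), 86.8361)

  agg2 <- aggregate_folds(folds_aug())
  expect_equal(round(agg2$accuracy, 3), 96.347)
  expect_equal(round(agg2$overall$precision, 4), 96.3581)
  # identical reports aggregate to themselves
  r <- folds_real()[[2]]
  same <- aggregate_folds(list(r, r, r))
  expect_equal(same$per_class$benign$precision, r$per_class$benign$precision)
  expect_equal(same$accuracy, r$accuracy)
  expect_error(aggregate_folds(list()), class = "lwunet_input_error")
})

test_that("improvement deltas reproduce the published gains", {
  imp <- improvement_report(aggregate_folds(folds_real()),
                            aggregate_folds(folds_aug()))
  expect_equal(unname(imp$overall$rounded["precision"]), 9.20)
  expect_equal(unname(imp$per_class$benign$rounded["recall"]), 11.80)
  expect_equal(unname(imp$per_class$malignant$rounded["precision"]), 10.88)
  expect_equal(unname(imp$per_class$benign$rounded["precision"]), 7.52)
  expect_equal(unname(imp$per_class$malignant$rounded["f1"]), 9.17)
  expect_equal(imp$accuracy$rounded, 9.48)
  a <- aggregate_folds(folds_real())
  zero <- improvement_report(a, a)
  expect_true(all(zero$overall$raw == 0))
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(99)
  worst <- 0
  for (rep in 1:20) {
    n <- 50
    y <- sample(c("benign", "malignant"), n, replace = TRUE)
    p <- ifelse(runif(n) < 0.7, y,
                sample(c("benign", "malignant"), n, replace = TRUE))
    if (length(unique(y)) < 2) next
    m <- class_metrics(confusion_matrix(y, p))
    ref <- caret::confusionMatrix(
      factor(p, levels = c("benign", "malignant")),
      factor(y, levels = c("benign", "malignant")),
      positive = "benign", mode = "prec_recall")
    worst <- max(worst,
                 abs(m$per_class$precision[1] / 100 - ref$byClass["Precision"]),
                 abs(m$per_class$recall[1] / 100 - ref$byClass["Recall"]),
                 abs(m$per_class$f1[1] / 100 - ref$byClass["F1"]),
                 abs(m$accuracy / 100 - ref$overall["Accuracy"]),
                 na.rm = TRUE)
  }
  expect_lt(worst, 1e-9)
})

test_that("F1 lies between precision and recall; accuracy equals weighted recall", {
  set.seed(17)
  for (rep in 1:50) {
    y <- sample(c("benign", "malignant"), 40, replace = TRUE)
    p <- sample(c("benign", "malignant"), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    m <- suppressWarnings(class_metrics(confusion_matrix(y, p)))
    for (i in 1:2) {
      pre <- m$per_class$precision[i]; rec <- m$per_class$recall[i]
      if (pre + rec > 0) {
        expect_gte(m$per_class$f1[i], min(pre, rec) - 1e-9)
        expect_lte(m$per_class$f1[i], max(pre, rec) + 1e-9)
      }
    }
    expect_equal(m$accuracy,
                 average_metrics(m$per_class$recall, m$per_class$support,
                                 "weighted"),
                 tolerance = 1e-9)
  }
})

test_that("reports serialize to JSON with the documented schema", {
  cm <- confusion_matrix(rep(c("benign", "malignant"), each = 5),
                         c(rep("benign", 4), "malignant",
                           rep("malignant", 4), "benign"))
  rep1 <- metrics_report(cm, fold = 1)
  f <- tempfile(fileext = ".json")
  write_metrics_json(rep1, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$fold, 1)
  expect_equal(back$per_class$benign$support, 5)
  expect_equal(back$accuracy, rep1$accuracy)
  expect_true(all(c("macro", "weighted") %in% names(back)))
})
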