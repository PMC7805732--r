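test_that("confusion matrices tally predictions against expert truth", {
  g <- kl_grades()
  cm <- confusion_from_predictions(g, g)
  expect_equal(unname(diag(cm)), rep(1L, 5))
  expect_equal(sum(cm), 5)

  cm <- confusion_from_predictions("Normal", "Severe")
  expect_equal(unname(cm["Normal", "Severe"]), 1L)
  expect_equal(sum(cm), 1)

  expect_error(confusion_from_predictions(g, g[1:3]),
               class = "km_invalid_argument")

  # 100 random pairs against a plain tally oracle.
  pred <- withr::with_seed(5, sample(g, 100, replace = TRUE))
  truth <- withr::with_seed(6, sample(g, 100, replace = TRUE))
  cm <- confusion_from_predictions(pred, truth)
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(unname(unclass(cm)[i, j]),
                   sum(pred == g[i] & truth == g[j]))
    }
  }
  expect_equal(unname(rowSums(cm)),
               vapply(g, function(x) sum(pred == x), numeric(1),
                      USE.NAMES = FALSE))
  expect_equal(unname(colSums(cm)),
               vapply(g, function(x) sum(truth == x), numeric(1),
                      USE.NAMES = FALSE))
})

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(diag(5) * 10L), 1)
  ref <- kl_reference_tables()
  expect_equal(overall_accuracy(ref$confusion_expert1), 1996 / 2000)
  expect_equal(overall_accuracy(ref$confusion_expert2), 1973 / 2000)
  expect_error(overall_accuracy(matrix(0L, 5, 5)),
               class = "km_degenerate_input")
})

test_that("reference tables are internally consistent", {
  ref <- kl_reference_tables()
  # Algorithm per-grade counts are the confusion-matrix row sums; expert
  # counts are the column sums.
  expect_equal(unname(rowSums(ref$confusion_expert1)),
               ref$grade_counts$algorithm_expert1)
  expect_equal(unname(colSums(ref$confusion_expert1)),
               ref$grade_counts$expert1)
  expect_equal(unname(rowSums(ref$confusion_expert2)),
               ref$grade_counts$algorithm_expert2)
  expect_equal(unname(colSums(ref$confusion_expert2)),
               ref$grade_counts$expert2)
  expect_equal(sum(ref$confusion_expert1), 2000)
  expect_equal(sum(ref$confusion_expert2), 2000)
})

test_that("precision/recall conventions swap denominators as documented", {
  ref <- kl_reference_tables()
  paper <- precision_recall(ref$confusion_expert1, "paper")
  std <- precision_recall(ref$confusion_expert1, "standard")
  # The two conventions are exact mirrors of each other.
  expect_equal(paper$precision, std$recall)
  expect_equal(paper$recall, std$precision)

  d <- precision_recall(as_kl_confusion(diag(5) * 4L), "standard")
  expect_equal(d$precision, rep(1, 5))
  expect_equal(d$recall, rep(1, 5))

  # Zero column for one grade: that grade's paper-precision is undefined.
  cm <- diag(5) * 3L
  cm[, 2] <- 0L
  pr <- precision_recall(as_kl_confusion(cm), "paper")
  expect_true(pr$undefined[2])
  expect_true(is.na(pr$precision[2]))
})

test_that("half-up rounding differs from banker's rounding at ties", {
  expect_equal(round_half_up(0.00005, 4), 1e-4)
  expect_equal(round_half_up(-0.00005, 4), -1e-4)
  expect_equal(round_half_up(0.961887, 4), 0.9619)
})
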