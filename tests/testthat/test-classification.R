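test_that("k-NN handles trivial cases and is deterministic", {
  one <- tibble::tibble(!!!stats::setNames(as.list(rnorm(7)),
                                           paste0("phi", 1:7)),
                        grade = "Moderate")
  m <- knn_fit(one, k = 1)
  probe <- matrix(rnorm(7 * 5), 5, 7)
  expect_true(all(knn_predict(m, probe) == "Moderate"))

  train <- make_cluster_data(10, seed = 1)
  m1 <- knn_fit(train, k = 3)
  m2 <- knn_fit(train, k = 3)
  probes <- make_cluster_data(4, seed = 2)
  expect_identical(knn_predict(m1, probes), knn_predict(m2, probes))

  expect_error(knn_fit(train, k = 0), class = "km_invalid_argument")
  expect_error(knn_fit(train, k = nrow(train) + 1),
               class = "km_invalid_argument")
})

test_that("k-NN ties break by summed distance then lowest ordinal grade", {
  x <- matrix(0, 2, 7)
  x[1, 1] <- -1
  x[2, 1] <- 1
  two <- as.data.frame(x)
  names(two) <- paste0("phi", 1:7)
  # Equidistant query, one vote each: the lower ordinal grade must win,
  # whatever order the training rows are given in.
  two$grade <- c("Severe", "Doubtful")
  m <- knn_fit(two, k = 2, standardize = FALSE)
  expect_equal(as.character(knn_predict(m, rep(0, 7))), "Doubtful")
  two$grade <- c("Doubtful", "Severe")
  m <- knn_fit(two, k = 2, standardize = FALSE)
  expect_equal(as.character(knn_predict(m, rep(0, 7))), "Doubtful")

  # Exact training point with k = 1 returns that point's label.
  train <- make_cluster_data(5, seed = 3)
  m <- knn_fit(train, k = 1)
  expect_identical(knn_predict(m, train[8, ]), train$grade[8])
})

test_that("k-NN predictions equal the exhaustive-distance oracle", {
  train <- make_cluster_data(12, seed = 10, sd_frac = 0.6) # overlapping
  queries <- make_cluster_data(40, seed = 11, sd_frac = 0.8)
  x <- as.matrix(train[, paste0("phi", 1:7)])
  for (k in c(1, 3, 5)) {
    for (metric in c("euclidean", "manhattan")) {
      m <- knn_fit(train, k = k, metric = metric, standardize = FALSE)
      got <- as.character(knn_predict(m, queries))
      want <- vapply(seq_len(nrow(queries)), function(i) {
        oracle_knn_predict(x, train$grade,
                           as.numeric(queries[i, paste0("phi", 1:7)]),
                           k = k, metric = metric)
      }, character(1))
      expect_identical(got, want)
    }
  }
})

test_that("k-NN separates five well-separated Gaussian clusters", {
  train <- make_cluster_data(20, seed = 30) # 100 training points
  test <- make_cluster_data(20, seed = 31) # 100 test points
  m <- knn_fit(train, k = 3)
  acc <- mean(knn_predict(m, test) == test$grade)
  expect_gte(acc, 0.95)
})

test_that("decision tree fits separable, pure, and noisy data sensibly", {
  # One threshold on phi1 separates the two classes: depth-1, accuracy 1.
  d <- make_cluster_data(10, seed = 40, sd_frac = 0.01)
  d <- d[d$grade %in% c("Normal", "Doubtful"), ]
  tr <- decision_tree_fit(d)
  expect_equal(tr$depth, 1L)
  expect_true(all(tree_predict(tr, d) == d$grade))

  pure <- d
  pure$grade <- kl_grade(rep("Mild", nrow(pure)))
  tr <- decision_tree_fit(pure)
  expect_equal(tr$depth, 0L)
  expect_true(all(tree_predict(tr, pure) == "Mild"))

  noisy <- make_cluster_data(10, seed = 41, sd_frac = 1.5)
  tr <- decision_tree_fit(noisy)
  baseline <- max(table(noisy$grade)) / nrow(noisy)
  expect_gte(mean(tree_predict(tr, noisy) == noisy$grade), baseline)

  expect_error(decision_tree_fit(noisy, max_depth = 0),
               class = "km_invalid_argument")
})

test_that("the tree matches rpart accuracy on clean separable data", {
  skip_if_not_installed("rpart")
  d <- make_cluster_data(15, seed = 50)
  tr <- decision_tree_fit(d)
  ours <- mean(tree_predict(tr, d) == d$grade)
  rp <- rpart::rpart(grade ~ ., data = d,
                     method = "class",
                     control = rpart::rpart.control(minsplit = 2, cp = 0))
  theirs <- mean(as.character(predict(rp, d, type = "class")) ==
                   as.character(d$grade))
  expect_equal(ours, theirs)
})

test_that("two-fold CV is stratified, seeded, and exact on one-hot features", {
  onehot <- tibble::tibble(
    phi1 = rep(c(1, 0, 0, 0, 0), 8), phi2 = rep(c(0, 1, 0, 0, 0), 8),
    phi3 = rep(c(0, 0, 1, 0, 0), 8), phi4 = rep(c(0, 0, 0, 1, 0), 8),
    phi5 = rep(c(0, 0, 0, 0, 1), 8), phi6 = 0, phi7 = 0,
    grade = kl_grade(rep(kl_grades(), 8))
  )
  cv <- two_fold_cv(onehot, seed = 7)
  expect_equal(cv$accuracy, 1)
  expect_true(all(unclass(cv$confusion)[!diag(5) == 1] == 0))

  cv2 <- two_fold_cv(onehot, seed = 7)
  expect_identical(unclass(cv$confusion), unclass(cv2$confusion))

  # Confusion marginals: columns are the true class counts, total is n.
  expect_equal(unname(colSums(cv$confusion)), rep(8, 5))
  expect_equal(sum(cv$confusion), nrow(onehot))

  short <- onehot[c(1:6), ]
  expect_error(two_fold_cv(short, seed = 1), class = "km_invalid_argument")
})

test_that("k-NN beats the tree on the five-cluster simulation, as expected", {
  d <- make_cluster_data(20, seed = 60)
  cvk <- two_fold_cv(d, "knn", seed = 4)
  cvt <- two_fold_cv(d, "tree", seed = 4)
  expect_gte(cvk$accuracy, 0.95)
  expect_gte(cvk$accuracy, cvt$accuracy)
})

test_that("tidy/glance methods expose CV results as tibbles", {
  d <- make_cluster_data(6, seed = 70)
  cv <- two_fold_cv(d, seed = 2)
  td <- tidy(cv)
  expect_equal(nrow(td), 25)
  expect_equal(sum(td$n), nrow(d))
  g <- glance(cv)
  expect_equal(g$accuracy, cv$accuracy)
  expect_equal(g$classifier, "knn")
})
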