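test_that("chi-square agreement reproduces the reference count tables", {
  ref <- kl_reference_tables()$grade_counts
  t1 <- chi_square_agreement(ref$algorithm_expert1, ref$expert1)
  expect_equal(t1$statistic, 0.006858, tolerance = 1e-6 / 0.006858)
  expect_equal(t1$decision, "accept-H0")
  expect_equal(t1$df, 4)
  # Expected counts are the per-grade averages of the two raters.
  expect_equal(t1$per_class$expected, c(650, 529, 279, 260, 282))

  t2 <- chi_square_agreement(ref$algorithm_expert2, ref$expert2)
  expect_equal(t2$statistic, 0.384018, tolerance = 1e-6 / 0.384018)
  expect_equal(t2$decision, "accept-H0")
  expect_equal(t2$per_class$expected[1:2], c(635.5, 543.5))
})

test_that("chi-square agreement is symmetric and zero iff counts agree", {
  a <- c(10, 20, 30, 40, 50)
  b <- c(12, 18, 33, 40, 47)
  expect_equal(chi_square_agreement(a, b)$statistic,
               chi_square_agreement(b, a)$statistic)
  expect_equal(chi_square_agreement(a, a)$statistic, 0)
  expect_gt(chi_square_agreement(a, b)$statistic, 0)
  expect_error(chi_square_agreement(c(0, 1, 1, 1, 1), c(0, 1, 1, 1, 1)),
               class = "km_degenerate_input")
})

test_that("the paired t statistic matches the printed formula and t.test", {
  ref <- kl_reference_tables()$grade_counts
  tt <- paired_t_agreement(ref$expert1, ref$expert2)
  expect_equal(tt$sum_d, 0)
  expect_equal(tt$sum_d_squared, 1058)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$decision, "accept-H0")
  expect_equal(tt$critical_value, 2.1318, tolerance = 1e-4)

  # Hand-derived case: D = (2, 0, 0, 0, -1) gives t = 0.2 / sqrt(4.8/20).
  x <- c(12, 10, 10, 10, 9)
  y <- c(10, 10, 10, 10, 10)
  tt <- paired_t_agreement(x, y)
  expect_equal(tt$statistic, 0.2 / sqrt(4.8 / 20), tolerance = 1e-9)
  # Independent route: stats::t.test computes the same paired statistic.
  expect_equal(tt$statistic,
               unname(stats::t.test(x, y, paired = TRUE)$statistic),
               tolerance = 1e-12)

  # Antisymmetry and the degenerate cases.
  expect_equal(paired_t_agreement(y, x)$statistic, -tt$statistic)
  expect_equal(paired_t_agreement(y, y)$statistic, 0)
  allsame <- paired_t_agreement(y + 3, y)
  expect_true(allsame$infinite)
  expect_equal(allsame$decision, "reject-H0")
})

test_that("critical values match distribution tables", {
  expect_equal(round(chi2_critical(4, 0.05), 5), 9.48773)
  expect_equal(round(chi2_critical(1, 0.05), 5), 3.84146)
  expect_equal(round(t_critical(4, 0.05, "one"), 4), 2.1318)
  expect_equal(round(t_critical(4, 0.05, "two"), 4), 2.7764)
  expect_equal(t_critical(1e6, 0.05, "one"), 1.6449, tolerance = 1e-4)
  expect_lt(chi2_critical(4, 0.999), 0.1)
  expect_error(chi2_critical(0, 0.05), class = "km_invalid_argument")
  expect_error(t_critical(4, 1.5), class = "km_invalid_argument")
})

test_that("decisions always agree with the statistic-vs-critical comparison", {
  for (seed in 1:20) {
    counts <- withr::with_seed(seed, list(
      a = sample(5:400, 5), b = sample(5:400, 5)
    ))
    chi <- chi_square_agreement(counts$a, counts$b)
    expect_equal(chi$decision == "accept-H0",
                 chi$statistic < chi$critical_value)
    tt <- paired_t_agreement(counts$a, counts$b)
    expect_equal(tt$decision == "accept-H0",
                 abs(tt$statistic) <= tt$critical_value)
  }
})

test_that("agreement tests tidy and glance into tibbles", {
  ref <- kl_reference_tables()$grade_counts
  chi <- chi_square_agreement(ref$algorithm_expert1, ref$expert1)
  expect_equal(nrow(tidy(chi)), 5)
  g <- glance(chi)
  expect_equal(g$method, "chi-square")
  expect_equal(g$statistic, chi$statistic)

  tt <- paired_t_agreement(ref$expert1, ref$expert2)
  expect_named(tidy(tt), c("grade", "x", "y", "d", "d_squared"))
  expect_equal(sum(tidy(tt)$d_squared), 1058)
})
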