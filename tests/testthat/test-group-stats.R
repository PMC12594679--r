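test_that("summarizeValues follows the mean +/- SEM convention", {
  expect_equal(summarizeValues(c(5, 5, 5)), list(mean = 5, sem = 0, n = 3L))
  s <- summarizeValues(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))      # sd = 1 (n-1 form)
  s1 <- summarizeValues(7)
  expect_equal(s1$mean, 7)
  expect_true(is.na(s1$sem))
  expect_error(summarizeValues(numeric()), "empty")
  expect_error(summarizeValues(c(1, NA)), "finite")
})

test_that("pooled t matches the closed form and stats::t.test", {
  r <- studentsTUnpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r@statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(pValue(r), 2 * pt(-abs(-3 / sqrt(2 / 3)), 4), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    a <- sample(0:30, 6, replace = TRUE) / 7
    b <- sample(0:30, 8, replace = TRUE) / 3
    if (var(a) + var(b) == 0) next
    mine <- studentsTUnpaired(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine@statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
  }
})

test_that("t test conventions: symmetry, antisymmetry, degenerate variance", {
  same <- studentsTUnpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(pValue(same), 1)
  ab <- studentsTUnpaired(c(1, 2, 3), c(4, 5, 6))
  ba <- studentsTUnpaired(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ab@statistic, -ba@statistic)
  expect_equal(pValue(ab), pValue(ba))
  expect_equal(pValue(studentsTUnpaired(c(2, 2), c(2, 2))), 1)
  expect_equal(pValue(studentsTUnpaired(c(2, 2), c(3, 3))), 0)
  expect_error(studentsTUnpaired(1, c(1, 2)), "n >= 2")
})

test_that("exact Mann-Whitney equals enumeration and wilcox.test", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r@statistic, 0)
  expect_equal(pValue(r), 0.1)          # 2/20 assignments
  expect_equal(r@method, "exact_enumeration")
  # all tie-free rank arrangements at several small sizes vs wilcox.test
  for (sz in list(c(3, 3), c(4, 3), c(4, 4))) {
    N <- sum(sz)
    for (s in asplit(combn(N, sz[1]), 2)) {
      a <- as.numeric(s)
      b <- as.numeric(setdiff(seq_len(N), s))
      mine <- mannWhitneyU(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
      expect_equal(mine@statistic, unname(ref$statistic))
    }
  }
})

test_that("Mann-Whitney conventions: identical groups, ordering invariance, ties", {
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 3 * 3 / 2)   # U = n_a n_b / 2 under identity
  expect_gt(pValue(same), 0.9)
  expect_match(same@method, "tie_corrected")
  set.seed(5)
  a <- rnorm(6); b <- rnorm(7)
  expect_equal(pValue(mannWhitneyU(a, b)),
               pValue(mannWhitneyU(sample(a), sample(b))))
  expect_error(mannWhitneyU(numeric(), 1), "non-empty")
})

test_that("normal approximation tracks the exact p at n = 7 vs 7", {
  set.seed(23)
  for (i in 1:15) {
    a <- rnorm(7); b <- rnorm(7, mean = runif(1, -1, 1))
    exact <- pValue(mannWhitneyU(a, b))                       # N = 14: exact
    approxSame <- {
      # force the approximation on the same data by exceeding N = 14
      u <- sum(rank(c(a, b))[1:7]) - 7 * 8 / 2
      mu <- 24.5; sig <- sqrt(7 * 7 * 15 / 12)
      min(1, 2 * pnorm(-abs((u - mu - sign(u - mu) * 0.5) / sig)))
    }
    expect_lt(abs(exact - approxSame), 0.02)
  }
})

test_that("compareMetricTable picks tests by the declared rule and errors usefully", {
  tbl <- data.frame(group = rep(c("nd", "d"), each = 9),
                    m = c(rnorm(9, 3), rnorm(9, 1)))
  r <- compareMetricTable(tbl, "m")
  expect_true(testUsed(r) %in% c("student_t_unpaired", "mann_whitney_u"))
  expect_equal(r@groupLabels, c("nd", "d"))
  small <- data.frame(group = rep(c("a", "b"), each = 3), m = rnorm(6))
  expect_equal(testUsed(compareMetricTable(small, "m")), "mann_whitney_u")
  forced <- compareMetricTable(tbl, "m", test = "student_t")
  expect_equal(testUsed(forced), "student_t_unpaired")
  expect_error(compareMetricTable(tbl, "nope"), "metric absent")
  expect_error(compareMetricTable(tbl[tbl$group == "nd", ], "m"),
               "missing group")
  tbl3 <- rbind(tbl, data.frame(group = "x", m = 1))
  expect_error(compareMetricTable(tbl3, "m"), "more than two")
})

test_that("significance flags and asterisks follow the p thresholds", {
  r <- studentsTUnpaired(c(1, 2, 3), c(4, 5, 6))   # p ~ 0.021
  expect_identical(unname(r@significantAt), c(TRUE, FALSE, FALSE))
  expect_equal(r@stars, "*")
  ns <- mannWhitneyU(c(1, 3, 5), c(2, 4, 6))
  expect_equal(ns@stars, "ns")
})
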