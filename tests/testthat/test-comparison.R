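test_that("U statistics match enumeration, including ties", {
  expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6))$u1, 0)
  expect_equal(mannWhitney(c(1, 3), c(2, 4))$u1, 1)
  tied <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$u1, 4.5)
  expect_equal(tied$u2, 4.5)
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("u1 + u2 = n1*n2 for arbitrary samples with ties", {
  set.seed(31)
  for (rep in 1:200) {
    x <- sample(1:6, sample(1:15, 1), replace = TRUE)
    y <- sample(1:6, sample(1:15, 1), replace = TRUE)
    mw <- mannWhitney(x, y)
    expect_equal(mw$u1 + mw$u2, mw$n1 * mw$n2)
  }
})

test_that("U and signed delta agree with brute-force pair counting", {
  set.seed(17)
  for (rep in 1:1000) {
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    x <- sample(seq(0, 5, 0.5), n1, replace = TRUE)
    y <- sample(seq(0, 5, 0.5), n2, replace = TRUE)
    bu <- bruteU(x, y)
    mw <- mannWhitney(x, y)
    expect_equal(mw$u1, bu$u1)
    expect_equal(cliffsDeltaSigned(x, y), bruteDelta(x, y), tolerance = 1e-12)
    # reported delta is minus the absolute signed delta when ties are absent
    if (!any(duplicated(c(x, y))))
      expect_equal(cliffsDeltaFromU(mw$uReport, n1, n2),
                   -abs(bruteDelta(x, y)), tolerance = 1e-12)
  }
})

test_that("exact two-sided test keeps its size near the nominal level", {
  set.seed(99)
  p <- replicate(10000, mannWhitney(rnorm(12), rnorm(12))$p)
  expect_lte(mean(p < 0.05), 0.055)
  expect_gte(mean(p < 0.05), 0.03)  # and is not vacuously conservative
})

test_that("exact and approximate p-values cross-check against wilcox.test", {
  set.seed(55)
  # tie-free small samples: exact path on both sides
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(mannWhitney(x, y)$p,
               stats::wilcox.test(x, y)$p.value, tolerance = 1e-12)
  # tied large samples: normal approximation with tie + continuity correction
  x <- sample(1:4, 36, replace = TRUE); y <- sample(1:4, 36, replace = TRUE)
  expect_equal(mannWhitney(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("delta from the reported U reproduces printed worked examples", {
  expect_equal(roundHalfUp(cliffsDeltaFromU(48, 12, 12), 3), -0.333)
  expect_equal(cliffsDeltaFromU(0, 12, 12), -1)
  expect_equal(cliffsDeltaFromU(72, 12, 12), 0)
  expect_error(cliffsDeltaFromU(10, 0, 5), "positive")
})

test_that("signed delta hits its boundary cases", {
  expect_equal(cliffsDeltaSigned(c(5, 6), c(1, 2)), 1)
  expect_equal(cliffsDeltaSigned(c(1, 2), c(1, 2)), 0)
  expect_equal(cliffsDeltaSigned(c(1, 3), c(2, 4)), -0.5)
})

test_that("magnitude bands respect the stated boundaries", {
  expect_equal(magnitudeClass(-0.333), "moderate")
  expect_equal(magnitudeClass(0.147), "minor")
  expect_equal(magnitudeClass(0.474), "large")
  expect_equal(magnitudeClass(0.1469), "negligible")
  expect_equal(magnitudeClass(0.3299), "minor")
  expect_equal(magnitudeClass(c(0, 1, -1)), c("negligible", "large", "large"))
})

test_that("conclusion codes combine direction, significance and magnitude", {
  up <- classifyChange(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(up$direction, "↑")
  expect_true(up$significant)
  expect_equal(up$magnitude, "large")
  expect_equal(up$conclusion, "↑ * +++")

  same <- classifyChange(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$conclusion, "| -")

  # exact median tie broken by the mean-rank difference
  tie <- classifyChange(c(1, 3, 4), c(2, 3, 5))
  expect_equal(stats::median(c(1, 3, 4)), stats::median(c(2, 3, 5)))
  expect_equal(tie$direction, "↑")
})

test_that("comparison rows render delta at 3 decimals, 4 when ambiguous", {
  cmp <- list(medianUngrazed = 2, medianGrazed = 3, u1 = 121.5, u2 = 22.5,
              uReport = 22.5, p = 0.003, delta = cliffsDeltaFromU(22.5, 12, 12),
              deltaSigned = 0.6875, magnitude = "large", direction = "↑",
              significant = TRUE, conclusion = "↑ * +++")
  row <- comparisonRow("General", "Large plant remains", cmp)
  expect_equal(row$delta_text, "-0.6875")  # -0.6875 is ambiguous at 3 d.p.
  cmp$delta <- cliffsDeltaFromU(48, 12, 12)
  expect_equal(comparisonRow("s", "v", cmp)$delta_text, "-0.333")
})
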