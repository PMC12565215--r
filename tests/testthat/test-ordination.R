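makeDivEnv <- function(n = 24, seed = 1) {
  set.seed(seed)
  units <- makeUnitKey("f", "grazed", paste0("Q", rep(1:(n / 4), each = 4)),
                       paste0("S", rep(1:4, n / 4)))
  div <- data.frame(unit = units, Div = runif(n), Eve = runif(n),
                    Ric = runif(n, 0, 2), N = 10L, S = 4L,
                    stringsAsFactors = FALSE)
  env <- data.frame(unit = units, lay1_cm = rgamma(n, 4, 2),
                    lay2_cm = rgamma(n, 4, 4), lay3_cm = rgamma(n, 4, 8),
                    remains_level = sample(1:4, n, TRUE),
                    stringsAsFactors = FALSE)
  env$lays_cm <- env$lay1_cm + env$lay2_cm + env$lay3_cm
  list(div = div, env = env)
}

test_that("feature matrix assembly joins, imputes and audits", {
  de <- makeDivEnv()
  m <- assembleMatrix(de$div, de$env)
  expect_equal(dim(m), c(24, 8))
  expect_equal(colnames(m), c("Div", "Eve", "Ric", "Lay1", "Lay2", "Lay3",
                              "Lays", "Rem"))
  expect_equal(unname(m[, "Lays"]), unname(m[, "Lay1"] + m[, "Lay2"] + m[, "Lay3"]))

  # orphan units are an error naming the missing side
  expect_error(assembleMatrix(de$div[-1, ], de$env), de$div$unit[1])

  # undefined evenness: imputed as 0, one warning, audit count matches
  div2 <- de$div
  div2$Eve[c(2, 5)] <- NA
  expect_warning(m2 <- assembleMatrix(div2, de$env), "imputed")
  expect_equal(sort(attr(m2, "imputedEve")), sort(div2$unit[c(2, 5)]))
  expect_equal(unname(m2[div2$unit[2], "Eve"]), 0)
  # or dropped on request
  m3 <- assembleMatrix(div2, de$env, naAction = "drop")
  expect_equal(nrow(m3), 22)
})

test_that("zero-variance columns are excluded with provenance", {
  de <- makeDivEnv()
  m <- assembleMatrix(de$div, de$env)
  m[, "Lay3"] <- 0
  m2 <- dropZeroVariance(m)
  expect_false("Lay3" %in% colnames(m2))
  expect_equal(attr(m2, "excluded"), "Lay3")
  # constant non-zero column is also excluded (variance, not value)
  m[, "Lay3"] <- 7
  expect_false("Lay3" %in% colnames(dropZeroVariance(m)))
  # no constant columns: identity
  m4 <- dropZeroVariance(assembleMatrix(de$div, de$env))
  expect_equal(ncol(m4), 8)
  expect_equal(attr(m4, "excluded"), character(0))
})

test_that("PCA is a standardised eigendecomposition with fixed signs", {
  de <- makeDivEnv(seed = 2)
  m <- dropZeroVariance(assembleMatrix(de$div, de$env))
  res <- surveyPca(m)
  # orthonormal loadings
  expect_equal(crossprod(res$loadings), diag(ncol(res$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # explained fractions sum to 1 and are non-increasing
  expect_equal(sum(res$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(res$explained) <= 1e-12))
  # reconstruction of the standardised matrix
  Z <- scale(m)
  expect_equal(unname(res$scores %*% t(res$loadings)),
               unname(Z[, colnames(m)]), tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude entry of each loading vector positive
  for (k in seq_len(ncol(res$loadings)))
    expect_gt(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
  # zero-variance input is rejected
  m0 <- cbind(m, Z0 = 1)
  expect_error(surveyPca(m0), "Z0")
})

test_that("PCA results do not depend on column order (up to the sign rule)", {
  de <- makeDivEnv(seed = 4)
  m <- assembleMatrix(de$div, de$env)
  r1 <- surveyPca(m)
  r2 <- surveyPca(m[, rev(colnames(m))])
  expect_equal(r1$explained, r2$explained, tolerance = 1e-10)
  expect_equal(abs(r1$loadings[colnames(m), ]), abs(r2$loadings[colnames(m), ]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two perfectly correlated columns load entirely on one component", {
  x <- rnorm(30)
  m <- cbind(a = x, b = 2 * x + 1)
  res <- surveyPca(m)
  expect_equal(res$explained[1], 1, tolerance = 1e-12)
})

test_that("planted correlations are recovered in loadings and summaries", {
  set.seed(77)
  n <- 72
  rem <- sample(1:4, n, TRUE)
  ric <- 0.9 * scale(rem)[, 1] + sqrt(1 - 0.81) * rnorm(n)
  div <- runif(n)
  lays <- -0.6 * div + rnorm(n, 2, 0.5)
  m <- cbind(Div = div, Ric = ric, Lays = lays, Rem = rem)
  res <- surveyPca(m)
  v1 <- res$loadings["Ric", 1:2]; v2 <- res$loadings["Rem", 1:2]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_lt(ang, 30)
  cs <- correlationSummary(m)
  rr <- cs[cs$var1 == "Div" & cs$var2 == "Lays", ]
  expect_lt(rr$r, 0)
  expect_match(cs[cs$var1 == "Ric" & cs$var2 == "Rem", "label"],
               "positive significant")
})

test_that("independent columns rarely show strong spurious correlation", {
  set.seed(123)
  hits <- replicate(100, {
    m <- cbind(a = rnorm(72), b = rnorm(72))
    abs(correlationSummary(m)$r) < 0.4
  })
  expect_gte(mean(hits), 0.95)
})
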