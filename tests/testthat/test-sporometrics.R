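test_that("degenerate and tallied measurement sets summarise correctly", {
  s <- summarizeMeasurements(rep(10, 40))
  expect_equal(c(s@d, s@e, s@f, s@g, s@h, s@j), rep(10, 6))
  expect_equal(s@i, 0)

  v <- rep(c(3.5, 4, 4.5, 5), c(10, 15, 10, 5))
  s2 <- summarizeMeasurements(v, nSporocarps = 2, nCollections = 2)
  expect_equal(s2@j, 4.0)                    # modal grid value
  expect_equal(s2@h, roundHalfUp(mean(v), 2))  # 4.13
  expect_gte(s2@e, 3.5); expect_lte(s2@f, 5)
  expect_gte(mean(v >= s2@e & v <= s2@f), 0.9)
  expect_error(summarizeMeasurements(5), "at least 2")
})

test_that("the interval covers >= 90% and each bound is grid-minimal", {
  set.seed(41)
  for (rep in 1:300) {
    v <- generateMeasurements(sample(10:120, 1), runif(1, 3, 12),
                              runif(1, 0.2, 2), grid = 0.5, seed = rep)
    s <- summarizeMeasurements(v)
    needed <- ceiling(0.9 * length(v) - 1e-9)
    inside <- function(e, f) sum(v >= e - 1e-9 & v <= f + 1e-9)
    expect_gte(inside(s@e, s@f), needed)
    # shrinking either bound by one grid step breaks coverage (when possible)
    if (s@e + 0.5 <= s@f) expect_lt(inside(s@e + 0.5, s@f), needed)
    if (s@f - 0.5 >= s@e) expect_lt(inside(s@e, s@f - 0.5), needed)
    expect_true(s@d <= s@e && s@e <= s@f && s@f <= s@g)
  }
})

test_that("notation strings format extremes conditionally and round-trip", {
  # extremes outside the main interval appear in parentheses
  v <- c(14.5, rep(15:19, each = 8), 19.5)
  s <- summarizeMeasurements(v, grid = 0.5)
  txt <- formatNotation(s)
  expect_match(txt, "\\(14\\.5\\) 15–19 \\(19\\.5\\)")
  # no parentheses when d = e and g = f
  s2 <- summarizeMeasurements(rep(c(3.5, 4, 4.5, 5), c(10, 15, 10, 5)))
  expect_false(grepl("\\(", formatNotation(s2)))
  expect_match(formatNotation(s2), "3\\.5–5 ")

  p <- parseNotation("{40/2/2} 3.5–5 [4.40 ± 0.49, 4.00]")
  expect_equal(c(p@a, p@b, p@c), c(40L, 2L, 2L))
  expect_equal(c(p@e, p@f, p@h, p@i, p@j), c(3.5, 5, 4.40, 0.49, 4.00))
  expect_equal(p@d, 3.5)  # absent extreme defaults to the bound
  expect_error(parseNotation("{40/2} 3.5-5 [4.4 ± 0.5, 4]"), "malformed")
})

test_that("parse(format(s)) is the identity on random summaries", {
  set.seed(91)
  for (rep in 1:1000) {
    v <- generateMeasurements(sample(5:80, 1), runif(1, 2, 15),
                              runif(1, 0, 1.5), grid = 0.5, seed = 10000 + rep)
    s <- summarizeMeasurements(v, nSporocarps = sample(1:5, 1),
                               nCollections = sample(1:3, 1))
    p <- parseNotation(formatNotation(s))
    for (sl in c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"))
      expect_equal(methods::slot(p, sl), methods::slot(s, sl),
                   tolerance = 1e-9)
  }
})

test_that("shape ratios are computed per spore before summarising", {
  s <- shapeRatio(c(8, 9), c(4, 3))
  expect_equal(s@h, 2.5)                       # mean of {2, 3}
  expect_equal(c(s@e, s@f), c(2, 3))
  glob <- shapeRatio(rep(6, 10), rep(6, 10))
  expect_equal(c(glob@e, glob@f, glob@h, glob@j), c(1, 1, 1, 1))
  # bounds >= 1 whenever every length >= width
  set.seed(2)
  w <- runif(30, 3, 5); l <- w + runif(30, 0, 4)
  sr <- shapeRatio(l, w)
  expect_gte(sr@e, 1)
  expect_error(shapeRatio(c(4, 5), c(2, 0)), "positive")
})

test_that("measurement tables produce a full morphometric description", {
  set.seed(6)
  df <- data.frame(
    collection = rep(c("K1", "K2"), each = 20),
    sporocarp = rep(1:4, each = 10),
    length_um = generateMeasurements(40, 6.2, 0.4, seed = 1),
    width_um = generateMeasurements(40, 3.6, 0.3, seed = 2))
  out <- summarizeSpores(df)
  expect_equal(out$length@a, 40L)
  expect_equal(out$length@b, 4L)
  expect_equal(out$length@c, 2L)
  expect_match(out$text, "µm, Q = ")
})
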