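test_that("observation files round-trip and validation catches violations", {
  obs <- toyObservations()
  path <- withr::local_tempfile(fileext = ".csv")
  writeObservations(obs, path)
  back <- readObservations(path)
  expect_equal(back[names(obs)], obs)

  dup <- rbind(obs, obs[1, ])
  dupPath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, dupPath, row.names = FALSE)
  expect_error(readObservations(dupPath), "duplicate.*f/ungrazed/Q1/S1, A")

  bad <- obs; bad$individual_number[1] <- 0L
  expect_error(validateObservations(bad), "positive integer")
})

test_that("trait labels normalize case/plural/suffix variants and reject unknowns", {
  expect_identical(normalizeTrait("Wood saprotrophs", "trophic"), "wood saprotroph")
  expect_identical(normalizeTrait("Polyporoid fungi", "sporocarp"), "polyporoid")
  expect_identical(normalizeTrait("Ascomycetes", "sporocarp"), "ascomycete")
  expect_identical(normalizeTrait("Slime molds", "sporocarp"), "slime mold")
  expect_identical(normalizeTrait("east asian", "geographic"), "East Asian")
  expect_identical(normalizeTrait("Medical", "edibility"), "medicinal")
  expect_error(normalizeTrait("levitating", "trophic"), "invalid trophic.*levitating")
})

test_that("environment validation enforces ranges and derives the layer total", {
  env <- data.frame(unit = "f/ungrazed/Q1/S1", lay1_cm = 2, lay2_cm = 1,
                    lay3_cm = 0.5, remains_level = 2L)
  out <- validateEnvironment(env)
  expect_equal(out$lays_cm, 3.5)
  env$remains_level <- 5L
  expect_error(validateEnvironment(env), "remains_level.*5")
  env$remains_level <- 2L; env$lay1_cm <- -1
  expect_error(validateEnvironment(env), "lay1_cm")
})

test_that("aggregateCounts reproduces hand-enumerated stratum summaries", {
  # one unit, one species with code 3
  a1 <- aggregateCounts(data.frame(unit = "f/ungrazed/Q1/S1", species = "A",
                                   individual_number = 3L))
  expect_equal(a1$N, 3L); expect_equal(a1$S, 1L)
  expect_equal(unname(a1$q["A"]), 1L); expect_equal(a1$Q, 1L)

  # two units, A in both (2 and 1), B in one (1)
  a2 <- aggregateCounts(toyObservations())
  expect_equal(a2$N, 4L); expect_equal(a2$S, 2L)
  expect_equal(unname(a2$q[c("A", "B")]), c(2L, 1L)); expect_equal(a2$Q, 2L)

  # disjoint species sets across units: S adds up
  obs <- data.frame(unit = rep(c("f/ungrazed/Q1/S1", "f/ungrazed/Q1/S2"), each = 2),
                    species = c("A", "B", "C", "D"), individual_number = 1L)
  a3 <- aggregateCounts(obs)
  perUnitS <- vapply(a3$perUnit, function(v) sum(v > 0), integer(1))
  expect_equal(a3$S, sum(perUnitS))

  expect_error(aggregateCounts(toyObservations(), forest = "nowhere"),
               "empty stratum")
})

test_that("quadrat-level aggregation pools subquadrats by summing and OR-ing", {
  obs <- data.frame(
    unit = c("f/grazed/Q1/S1", "f/grazed/Q1/S2", "f/grazed/Q2/S1"),
    species = c("A", "A", "A"), individual_number = c(2L, 3L, 1L))
  a <- aggregateCounts(obs, level = "quadrat")
  expect_equal(a$Q, 2L)
  expect_equal(unname(a$q["A"]), 2L)           # present in both quadrats
  expect_equal(unname(a$perUnit[["f/grazed/Q1"]]["A"]), 5L)
})

test_that("count conservation holds over any partition into strata", {
  set.seed(42)
  ds <- generateDataset(simulationConfig(seed = 42))
  total <- aggregateCounts(ds$survey)
  byStratum <- lapply(ds$survey@design@forestTypes, function(f)
    lapply(c("grazed", "ungrazed"), function(tr)
      aggregateCounts(ds$survey, forest = f, treatment = tr)))
  expect_equal(sum(unlist(lapply(byStratum, function(l) vapply(l, `[[`, numeric(1), "N")))),
               total$N)
  # q_i <= Q and n_i >= q_i (presence implies >= 1 individual per unit)
  expect_true(all(total$q <= total$Q))
  expect_true(all(total$n >= total$q))
})

test_that("venn partition satisfies set algebra, including the 17/53/16 fixture", {
  g <- paste0("g", 1:70)             # 17 shared + 53 unique
  u <- c(paste0("g", 1:17), paste0("u", 1:16))
  v <- vennPartition(g, u)
  expect_equal(v$shared, 17); expect_equal(v$uniqueGrazed, 53)
  expect_equal(v$uniqueUngrazed, 16)
  expect_equal(v$total, 86); expect_equal(v$nGrazed, 70); expect_equal(v$nUngrazed, 33)

  same <- vennPartition(letters, letters)
  expect_equal(same$uniqueGrazed, 0); expect_equal(same$total, same$shared)
  disj <- vennPartition(letters[1:3], letters[4:6])
  expect_equal(disj$shared, 0)

  set.seed(7)
  for (rep in 1:50) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    v <- vennPartition(a, b)
    expect_equal(v$total, length(union(a, b)))
    expect_equal(v$nGrazed + v$nUngrazed - v$shared, v$total)  # inclusion-exclusion
  }
})

test_that("wide matrices convert to the long format losslessly", {
  m <- matrix(c(2, 0, 1, 3), 2, 2,
              dimnames = list(c("A", "B"),
                              c("f/grazed/Q1/S1", "f/grazed/Q1/S2")))
  long <- wideToLong(m)
  expect_equal(nrow(long), 3)
  a <- aggregateCounts(long)
  expect_equal(unname(a$n[c("A", "B")]), c(3L, 3L))
})

test_that("the survey container validates cross-table consistency", {
  obs <- toyObservations()
  traits <- toyTraits(c("A", "B"))
  env <- data.frame(unit = unique(obs$unit), lay1_cm = 1, lay2_cm = 0.5,
                    lay3_cm = 0, remains_level = 2L)
  s <- fungalSurvey(obs, traits, env)
  expect_s4_class(s, "FungalSurvey")
  expect_equal(nrow(observations(s)), 3)
  expect_equal(surveyDesignOf(s)@forestTypes, "f")
  # missing trait row is an error
  expect_error(fungalSurvey(obs, toyTraits("A"), env), "without trait rows")
})
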