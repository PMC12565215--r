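#' Synthetic survey configuration
#'
#' Parameters of the seeded survey generator. The defaults emulate the
#' study conditions of a two-year silvopasture contrast: three forest
#' types, 12 sampling units per plot type, a species pool partitioned into
#' 17 shared / 53 grazed-only / 16 ungrazed-only species, a geometric-series
#' abundance model whose concentration parameter theta contrasts a
#' monopolistically dominated ungrazed community (theta = 0.8) with a more
#' balanced grazed one (theta = 0.3), occupancy increasing with relative
#' abundance, treatment-dependent trait frequencies (alga symbionts
#' dominant ungrazed, wood saprotrophs dominant grazed; ungrazed-pool
#' geographic components restricted to cosmopolitan/pantropical), and
#' environmental covariates: litterfall layers multiplied by 0.5 under
#' grazing and the plant-remains level shifted up by one.
#'
#' @slot seed integer RNG seed.
#' @slot forestTypes forest-type labels.
#' @slot unitsPerPlot sampling units (subquadrats) per plot type.
#' @slot venn integer vector \code{c(shared, uniqueGrazed, uniqueUngrazed)}.
#' @slot thetaUngrazed,thetaGrazed geometric-series concentration in (0,1).
#' @slot basePresence per-individual base occupancy probability in (0,1).
#' @slot meanIndividualsPerUnit expected individuals per sampling unit.
#' @slot litterFactor multiplicative change of litter thickness under
#'   grazing.
#' @slot remainsShift additive ordinal shift of the remains level under
#'   grazing.
#' @slot litterMeans named list: per forest type, ungrazed mean thickness
#'   (cm) of the three layers.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  forestTypes = "character",
  unitsPerPlot = "integer",
  venn = "integer",
  thetaUngrazed = "numeric",
  thetaGrazed = "numeric",
  basePresence = "numeric",
  meanIndividualsPerUnit = "numeric",
  litterFactor = "numeric",
  remainsShift = "integer",
  litterMeans = "list"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (any(object@venn < 0) || length(object@venn) != 3)
    msgs <- c(msgs, "venn must be 3 non-negative counts")
  if (sum(object@venn) < 1)
    msgs <- c(msgs, "species pool must be non-empty")
  for (th in c(object@thetaUngrazed, object@thetaGrazed))
    if (th <= 0 || th >= 1) msgs <- c(msgs, "theta must lie in (0,1)")
  if (object@basePresence <= 0 || object@basePresence >= 1)
    msgs <- c(msgs, "basePresence must lie in (0,1)")
  if (object@unitsPerPlot < 1) msgs <- c(msgs, "unitsPerPlot must be positive")
  if (!all(object@forestTypes %in% names(object@litterMeans)))
    msgs <- c(msgs, "litterMeans must name every forest type")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed RNG seed.
#' @param forestTypes forest-type labels (default three types).
#' @param unitsPerPlot sampling units per plot type (default 12).
#' @param venn \code{c(shared, uniqueGrazed, uniqueUngrazed)} species
#'   counts (default \code{c(17, 53, 16)}).
#' @param thetaUngrazed,thetaGrazed abundance concentration per treatment
#'   (defaults 0.8 and 0.3).
#' @param basePresence base occupancy rate (default 0.15).
#' @param meanIndividualsPerUnit expected individuals per unit (default 12).
#' @param litterFactor grazing multiplier on litter thickness (default 0.5).
#' @param remainsShift grazing shift of the remains level (default 1).
#' @param litterMeans per-forest ungrazed layer means in cm; the default
#'   gives the secondary forest a thick three-layer litter and the two
#'   plantations a thin litter with no decomposed layer (so that layer is
#'   constant 0 there).
#' @return a \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             forestTypes = c("secondary_mixed",
                                             "dense_plantation",
                                             "sparse_plantation"),
                             unitsPerPlot = 12L,
                             venn = c(17L, 53L, 16L),
                             thetaUngrazed = 0.8,
                             thetaGrazed = 0.3,
                             basePresence = 0.15,
                             meanIndividualsPerUnit = 12,
                             litterFactor = 0.5,
                             remainsShift = 1L,
                             litterMeans = NULL) {
  if (is.null(litterMeans)) {
    litterMeans <- list(
      secondary_mixed = c(2.5, 1.25, 0.5),
      dense_plantation = c(1.0, 0.5, 0),
      sparse_plantation = c(1.0, 0.5, 0)
    )[forestTypes]
    # unseen forest labels fall back to a thin litter profile
    fill <- vapply(litterMeans, is.null, logical(1))
    litterMeans[fill] <- list(c(1.0, 0.5, 0))
    names(litterMeans) <- forestTypes
  }
  new("SimulationConfig",
      seed = as.integer(seed), forestTypes = as.character(forestTypes),
      unitsPerPlot = as.integer(unitsPerPlot), venn = as.integer(venn),
      thetaUngrazed = thetaUngrazed, thetaGrazed = thetaGrazed,
      basePresence = basePresence,
      meanIndividualsPerUnit = meanIndividualsPerUnit,
      litterFactor = litterFactor, remainsShift = as.integer(remainsShift),
      litterMeans = litterMeans)
}

# geometric-series relative abundances for S species at concentration theta
.geometricSeries <- function(S, theta) {
  if (S == 1) return(1)
  p <- theta * (1 - theta)^(seq_len(S) - 1)
  p / sum(p)
}

# treatment-dependent trait frequency tables
.traitFreqs <- function(treatment) {
  if (treatment == "ungrazed") {
    list(
      trophic = c("alga symbiont" = 0.35, "wood saprotroph" = 0.30,
                  "soil saprotroph" = 0.15, "plant symbiont" = 0.10,
                  "insect symbiont" = 0.05, "fungus symbiont" = 0.05),
      attachment = c("wood-inhabiting" = 0.75, "soil-inhabiting" = 0.25),
      sporocarp = c("ascomycete" = 0.40, "agaricoid" = 0.20,
                    "polyporoid" = 0.20, "clavarioid" = 0.08,
                    "boletoid" = 0.04, "jelly" = 0.04, "gastroid" = 0.02,
                    "cantharelloid" = 0.01, "slime mold" = 0.01),
      geographic = c("cosmopolitan" = 0.70, "pantropical" = 0.30),
      edibility = c("unknown" = 0.80, "edible" = 0.08, "medicinal" = 0.07,
                    "poisonous" = 0.05),
      order = c("Ostropales" = 0.35, "Polyporales" = 0.25,
                "Agaricales" = 0.20, "Lepidostromatales" = 0.08,
                "Russulales" = 0.06, "Xylariales" = 0.06)
    )
  } else {
    list(
      trophic = c("wood saprotroph" = 0.45, "soil saprotroph" = 0.20,
                  "alga symbiont" = 0.10, "plant symbiont" = 0.10,
                  "insect symbiont" = 0.08, "fungus symbiont" = 0.07),
      attachment = c("wood-inhabiting" = 0.60, "soil-inhabiting" = 0.40),
      sporocarp = c("agaricoid" = 0.30, "polyporoid" = 0.25,
                    "ascomycete" = 0.20, "clavarioid" = 0.06,
                    "boletoid" = 0.06, "jelly" = 0.05, "gastroid" = 0.04,
                    "cantharelloid" = 0.02, "slime mold" = 0.02),
      geographic = c("cosmopolitan" = 0.55, "pantropical" = 0.25,
                     "north temperate" = 0.12, "East Asian" = 0.08),
      edibility = c("unknown" = 0.60, "edible" = 0.20, "medicinal" = 0.12,
                    "poisonous" = 0.08),
      order = c("Agaricales" = 0.30, "Polyporales" = 0.28,
                "Ostropales" = 0.18, "Russulales" = 0.10,
                "Xylariales" = 0.08, "Lepidostromatales" = 0.06)
    )
  }
}

#' Generate a complete synthetic survey dataset
#'
#' Deterministic given the config seed. Species pools realise the
#' configured shared/unique partition exactly (every pool species is forced
#' to occur at least once in its treatment); per-treatment abundances follow
#' a geometric series ranked by a seeded permutation; per-unit presence is
#' Bernoulli with probability \eqn{1 - (1 - \pi)^{\lambda_i}} where
#' \eqn{\lambda_i} is the species' expected per-unit abundance; present
#' species get an individual-number code in 1-4 weighted towards higher
#' codes for abundant species. Environment covariates follow the configured
#' grazing effects.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return list with \code{survey} (a \code{\link{FungalSurvey}}) and
#'   \code{truth} (species pools, per-treatment abundance models and the
#'   configured effect directions).
#' @export
generateDataset <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)

  nShared <- config@venn[1]; nG <- config@venn[2]; nU <- config@venn[3]
  total <- nShared + nG + nU
  species <- sprintf("sp%03d", seq_len(total))
  sharedSp <- species[seq_len(nShared)]
  grazedOnly <- species[nShared + seq_len(nG)]
  ungrazedOnly <- species[nShared + nG + seq_len(nU)]
  pools <- list(
    grazed = c(sharedSp, grazedOnly),
    ungrazed = c(sharedSp, ungrazedOnly)
  )

  # trait catalog: ungrazed-pool species draw from the ungrazed frequency
  # tables (keeping its geographic components restricted), grazed-only
  # species from the grazed tables
  sampleTraits <- function(sp, treatment) {
    fr <- .traitFreqs(treatment)
    data.frame(
      species = sp,
      order = sample(names(fr$order), length(sp), TRUE, fr$order),
      trophic = sample(names(fr$trophic), length(sp), TRUE, fr$trophic),
      attachment = sample(names(fr$attachment), length(sp), TRUE, fr$attachment),
      sporocarp = sample(names(fr$sporocarp), length(sp), TRUE, fr$sporocarp),
      geographic = sample(names(fr$geographic), length(sp), TRUE, fr$geographic),
      edibility = sample(names(fr$edibility), length(sp), TRUE, fr$edibility),
      stringsAsFactors = FALSE
    )
  }
  traits <- rbind(
    sampleTraits(c(sharedSp, ungrazedOnly), "ungrazed"),
    sampleTraits(grazedOnly, "grazed")
  )
  traits <- traits[order(traits$species), , drop = FALSE]
  rownames(traits) <- NULL

  # per-treatment geometric abundance models (rank permutation seeded)
  theta <- c(ungrazed = config@thetaUngrazed, grazed = config@thetaGrazed)
  relAbund <- lapply(c("ungrazed", "grazed"), function(tr) {
    sp <- sample(pools[[tr]])            # random dominance ranking
    stats::setNames(.geometricSeries(length(sp), theta[[tr]]), sp)
  })
  names(relAbund) <- c("ungrazed", "grazed")

  units <- expand.grid(
    subquadrat = seq_len(4), quadrat = seq_len(ceiling(config@unitsPerPlot / 4)),
    treatment = c("ungrazed", "grazed"), forest = config@forestTypes,
    stringsAsFactors = FALSE
  )
  # keep exactly unitsPerPlot units per forest x treatment
  units$idx <- stats::ave(seq_len(nrow(units)),
                          units$forest, units$treatment, FUN = seq_along)
  units <- units[units$idx <= config@unitsPerPlot, , drop = FALSE]
  units$unit <- makeUnitKey(units$forest, units$treatment,
                            paste0("Q", units$quadrat),
                            paste0("S", units$subquadrat))

  obsRows <- vector("list", nrow(units))
  for (k in seq_len(nrow(units))) {
    tr <- units$treatment[k]
    ra <- relAbund[[tr]]
    lambda <- config@meanIndividualsPerUnit * ra
    pPresent <- 1 - (1 - config@basePresence)^lambda
    present <- stats::runif(length(ra)) < pPresent
    if (!any(present)) next
    codeProb <- pmin(0.85, lambda[present] / (lambda[present] + 2))
    codes <- 1L + stats::rbinom(sum(present), 3L, codeProb)
    obsRows[[k]] <- data.frame(
      unit = units$unit[k], species = names(ra)[present],
      individual_number = codes, stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, obsRows)

  # force every pool species to occur at least once in its treatment
  for (tr in c("ungrazed", "grazed")) {
    seen <- unique(obs$species[grepl(sprintf("/%s/", tr), obs$unit)])
    missing <- setdiff(pools[[tr]], seen)
    if (length(missing)) {
      trUnits <- units$unit[units$treatment == tr]
      add <- data.frame(
        unit = sample(trUnits, length(missing), replace = TRUE),
        species = missing, individual_number = 1L, stringsAsFactors = FALSE
      )
      # merge, keeping existing rows on collision
      key <- paste(obs$unit, obs$species)
      add <- add[!paste(add$unit, add$species) %in% key, , drop = FALSE]
      obs <- rbind(obs, add)
    }
  }
  obs <- obs[order(obs$unit, obs$species), , drop = FALSE]
  rownames(obs) <- NULL

  # environment: gamma-distributed layer thicknesses on a 0.25 cm grid,
  # grazing multiplies the mean; ordinal remains level shifted by grazing
  envRows <- lapply(seq_len(nrow(units)), function(k) {
    f <- units$forest[k]; tr <- units$treatment[k]
    mns <- config@litterMeans[[f]]
    fac <- if (tr == "grazed") config@litterFactor else 1
    lay <- vapply(mns * fac, function(mu) {
      if (mu <= 0) return(0)
      roundHalfUp(stats::rgamma(1, shape = 4, rate = 4 / mu) / 0.25) * 0.25
    }, numeric(1))
    base <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
    rem <- if (tr == "grazed") min(4L, base + config@remainsShift) else base
    data.frame(unit = units$unit[k], lay1_cm = lay[1], lay2_cm = lay[2],
               lay3_cm = lay[3], remains_level = as.integer(rem),
               stringsAsFactors = FALSE)
  })
  env <- do.call(rbind, envRows)

  survey <- fungalSurvey(obs, traits, env,
                         design = surveyDesign(config@forestTypes))
  truth <- list(
    seed = config@seed,
    pools = pools,
    relAbund = relAbund,
    effects = list(
      richness = if (nG + nShared > nU + nShared) "up" else if
        (nG < nU) "down" else "none",
      litterfall = if (config@litterFactor < 1) "down" else if
        (config@litterFactor > 1) "up" else "none",
      remains = if (config@remainsShift > 0) "up" else if
        (config@remainsShift < 0) "down" else "none"
    )
  )
  list(survey = survey, truth = truth)
}

#' Generate planted sporocarp point patterns
#'
#' Produces point sets with known cluster structure for validating the
#' individual-number coding: cluster centres separated by more than the
#' 2 m linkage cut, members chained with nearest-neighbour gaps drawn to
#' realise a known code.
#'
#' @param nClusters number of planted clusters.
#' @param codes optional integer vector in 1-4, one per cluster; sampled
#'   uniformly when omitted.
#' @param seed RNG seed.
#' @return list with \code{points} (data.frame x, y, cluster) and
#'   \code{codes} (the planted per-cluster codes, in cluster order).
#' @export
generatePoints <- function(nClusters = 3, codes = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(codes)) codes <- sample(1:4, nClusters, replace = TRUE)
  if (length(codes) != nClusters || any(!codes %in% 1:4))
    validationError("codes must be one value in 1..4 per cluster")
  # centres on a coarse lattice, >= 6 m apart, so clusters never chain
  centres <- cbind(x = 6 * seq_len(nClusters), y = 6 * (seq_len(nClusters) %% 7))
  gapRange <- list(`1` = NULL, `2` = c(0.05, 0.5), `3` = c(0.55, 1.0),
                   `4` = c(1.05, 2.0))
  pts <- lapply(seq_len(nClusters), function(k) {
    code <- codes[k]
    if (code == 1L)
      return(data.frame(x = centres[k, 1], y = centres[k, 2], cluster = k))
    nm <- sample(2:4, 1)
    gr <- gapRange[[as.character(code)]]
    # chain members along a line; the largest gap realises the code band,
    # the others stay at or below it
    gaps <- c(stats::runif(1, gr[1], gr[2]),
              stats::runif(nm - 2, 0.05, gr[2]))
    xs <- centres[k, 1] + cumsum(c(0, gaps))
    data.frame(x = xs, y = rep(centres[k, 2], nm), cluster = k)
  })
  list(points = do.call(rbind, pts), codes = codes)
}

#' Generate grid-snapped normal measurements
#'
#' @param n number of draws (>= 2).
#' @param mean,sd normal parameters (sd >= 0).
#' @param grid recording grid (default 0.5).
#' @param seed RNG seed.
#' @return numeric vector of positive, grid-snapped values.
#' @export
generateMeasurements <- function(n, mean, sd, grid = 0.5, seed = 1L) {
  if (n < 2) validationError("n must be >= 2")
  if (sd < 0) validationError("sd must be >= 0")
  set.seed(seed)
  v <- stats::rnorm(n, mean, sd)
  v <- pmax(grid, roundHalfUp(v / grid) * grid)
  v
}
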