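#' Aggregate observations into stratum abundance summaries
#'
#' Pools the long observation records for one stratum (a subset of forest
#' types crossed with a subset of treatments) at the chosen analysis level
#' and returns the quantities every downstream statistic consumes: species
#' abundances n_i (summed individual-number codes), total abundance N,
#' species count S, per-species occupancy q_i (number of sampling units in
#' which species i occurs) and the number of units Q in the stratum.
#'
#' At \code{level = "quadrat"} the subquadrats of each quadrat are pooled by
#' summing individual numbers (presence is the OR over subquadrats).
#'
#' @param obs observations data.frame or a \code{FungalSurvey}.
#' @param forest forest type(s) to keep; \code{NULL} keeps all.
#' @param treatment treatment(s) to keep; \code{NULL} keeps all.
#' @param level \code{"subquadrat"} (default) or \code{"quadrat"}.
#' @param allUnits optional character vector of all sampling-unit keys that
#'   exist in the stratum (e.g. from the environment table), so that units
#'   with no fungal records still count towards Q. Defaults to the units
#'   seen in \code{obs}.
#' @return list with elements \code{n} (named species abundance vector),
#'   \code{q} (named occupancy vector), \code{N}, \code{S}, \code{Q},
#'   \code{units} (unit keys at the analysis level) and \code{perUnit}
#'   (named list of per-unit species abundance vectors).
#' @export
aggregateCounts <- function(obs, forest = NULL, treatment = NULL,
                            level = c("subquadrat", "quadrat"),
                            allUnits = NULL) {
  level <- match.arg(level)
  if (methods::is(obs, "FungalSurvey")) {
    if (is.null(allUnits)) allUnits <- obs@environment$unit
    obs <- obs@observations
  }
  keys <- parseUnitKeys(obs$unit)
  keep <- rep(TRUE, nrow(obs))
  if (!is.null(forest)) keep <- keep & keys$forest %in% forest
  if (!is.null(treatment)) keep <- keep & keys$treatment %in% treatment
  obs <- obs[keep, , drop = FALSE]
  keys <- keys[keep, , drop = FALSE]

  unitPool <- if (is.null(allUnits)) obs$unit else {
    ak <- parseUnitKeys(allUnits)
    sel <- rep(TRUE, length(allUnits))
    if (!is.null(forest)) sel <- sel & ak$forest %in% forest
    if (!is.null(treatment)) sel <- sel & ak$treatment %in% treatment
    allUnits[sel]
  }
  if (level == "quadrat") {
    obsUnit <- keys$quadrat_key
    unitPool <- unique(parseUnitKeys(unitPool)$quadrat_key)
  } else {
    obsUnit <- obs$unit
    unitPool <- unique(unitPool)
  }
  if (length(unitPool) == 0)
    validationError("empty stratum: no sampling units match the filter")

  if (nrow(obs) == 0) {
    empty <- stats::setNames(integer(0), character(0))
    return(list(
      n = empty, q = empty, N = 0L, S = 0L, Q = length(unique(unitPool)),
      units = unique(unitPool),
      perUnit = stats::setNames(
        rep(list(empty), length(unique(unitPool))), unique(unitPool)),
      level = level, forest = forest, treatment = treatment
    ))
  }

  # pool duplicate (unit, species) created by quadrat-level merging
  n_by <- tapply(obs$individual_number, list(obsUnit, obs$species), sum)
  perUnit <- stats::setNames(lapply(unitPool, function(u) {
    if (!u %in% rownames(n_by)) return(stats::setNames(integer(0), character(0)))
    v <- n_by[u, , drop = FALSE]
    keep <- !is.na(v[1, ])
    stats::setNames(as.integer(v[1, keep]), colnames(v)[keep])
  }), unitPool)

  n <- tapply(obs$individual_number, obs$species, sum)
  n <- stats::setNames(as.integer(n), names(n))
  pres <- unique(data.frame(unit = obsUnit, species = obs$species))
  q <- table(factor(pres$species, levels = names(n)))
  q <- stats::setNames(as.integer(q), names(n))

  list(
    n = n, q = q,
    N = sum(n), S = sum(n > 0L), Q = length(unitPool),
    units = unitPool, perUnit = perUnit,
    level = level, forest = forest, treatment = treatment
  )
}

#' Two-treatment species-set partition
#'
#' Splits the species pools of the grazed and ungrazed treatments into
#' shared and treatment-unique sets (the two-set Venn decomposition).
#'
#' @param speciesGrazed,speciesUngrazed character vectors (or sets) of
#'   species identifiers.
#' @return list with \code{shared}, \code{uniqueGrazed},
#'   \code{uniqueUngrazed} (counts), \code{total}, \code{nGrazed},
#'   \code{nUngrazed}, and the member sets \code{sharedSpecies},
#'   \code{uniqueGrazedSpecies}, \code{uniqueUngrazedSpecies}.
#' @examples
#' vennPartition(letters[1:5], letters[4:8])
#' @export
vennPartition <- function(speciesGrazed, speciesUngrazed) {
  g <- unique(as.character(speciesGrazed))
  u <- unique(as.character(speciesUngrazed))
  shared <- intersect(g, u)
  og <- setdiff(g, u)
  ou <- setdiff(u, g)
  list(
    shared = length(shared),
    uniqueGrazed = length(og),
    uniqueUngrazed = length(ou),
    total = length(shared) + length(og) + length(ou),
    nGrazed = length(g),
    nUngrazed = length(u),
    sharedSpecies = sort(shared),
    uniqueGrazedSpecies = sort(og),
    uniqueUngrazedSpecies = sort(ou)
  )
}
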