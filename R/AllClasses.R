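#' @import methods
NULL

## Canonical category enumerations for the trait catalog. Labels follow the
## survey variable scheme: six trophic modes, two substrate attachment modes,
## nine sporocarp morphotypes, four geographic distribution components and
## four edibility classes.

TRAIT_LEVELS <- list(
  trophic = c(
    "soil saprotroph", "wood saprotroph", "alga symbiont",
    "plant symbiont", "insect symbiont", "fungus symbiont"
  ),
  attachment = c("soil-inhabiting", "wood-inhabiting"),
  sporocarp = c(
    "agaricoid", "boletoid", "polyporoid", "cantharelloid",
    "clavarioid", "gastroid", "jelly", "ascomycete", "slime mold"
  ),
  geographic = c("cosmopolitan", "north temperate", "pantropical", "East Asian"),
  edibility = c("edible", "medicinal", "poisonous", "unknown")
)

TRAIT_AXES <- c("order", "trophic", "attachment", "sporocarp", "geographic",
                "edibility")

#' Nested survey design
#'
#' Describes the sampling layout: forest types crossed with a grazed and an
#' ungrazed treatment; within each plot type, quadrats subdivided into
#' subquadrats, the subquadrat being the minimum recording unit. With the
#' defaults (3 quadrats of 400 m2, each split into 4 subquadrats of 100 m2)
#' a plot type holds 12 sampling units.
#'
#' @slot forestTypes character vector of forest-type labels.
#' @slot treatments character vector, always \code{c("ungrazed", "grazed")}.
#' @slot quadratsPerPlot integer, quadrats per plot type.
#' @slot subquadratsPerQuadrat integer, subquadrats per quadrat.
#' @slot quadratArea numeric, quadrat area in m2.
#' @slot subquadratArea numeric, subquadrat area in m2.
#' @slot analysisLevel \code{"subquadrat"} or \code{"quadrat"}.
#' @export
setClass("SurveyDesign", representation(
  forestTypes = "character",
  treatments = "character",
  quadratsPerPlot = "integer",
  subquadratsPerQuadrat = "integer",
  quadratArea = "numeric",
  subquadratArea = "numeric",
  analysisLevel = "character"
))

setValidity("SurveyDesign", function(object) {
  msgs <- character()
  if (length(object@forestTypes) < 1 || anyDuplicated(object@forestTypes))
    msgs <- c(msgs, "forestTypes must be a non-empty set of unique labels")
  if (!identical(sort(object@treatments), sort(c("grazed", "ungrazed"))))
    msgs <- c(msgs, "treatments must be exactly {grazed, ungrazed}")
  if (object@quadratsPerPlot < 1L || object@subquadratsPerQuadrat < 1L)
    msgs <- c(msgs, "quadrat and subquadrat counts must be positive")
  if (abs(object@subquadratsPerQuadrat * object@subquadratArea -
          object@quadratArea) > 1e-9)
    msgs <- c(msgs, "subquadrat count x subquadrat area must equal quadrat area")
  if (!object@analysisLevel %in% c("subquadrat", "quadrat"))
    msgs <- c(msgs, "analysisLevel must be 'subquadrat' or 'quadrat'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a survey design
#'
#' @param forestTypes forest-type labels.
#' @param quadratsPerPlot quadrats per plot type (default 3).
#' @param subquadratsPerQuadrat subquadrats per quadrat (default 4).
#' @param quadratArea quadrat area in m2 (default 400).
#' @param analysisLevel default analysis level, \code{"subquadrat"} or
#'   \code{"quadrat"}.
#' @return a \code{SurveyDesign} object.
#' @examples
#' surveyDesign(c("secondary_mixed", "dense_plantation", "sparse_plantation"))
#' @export
surveyDesign <- function(forestTypes,
                         quadratsPerPlot = 3L,
                         subquadratsPerQuadrat = 4L,
                         quadratArea = 400,
                         analysisLevel = "subquadrat") {
  new("SurveyDesign",
      forestTypes = as.character(forestTypes),
      treatments = c("ungrazed", "grazed"),
      quadratsPerPlot = as.integer(quadratsPerPlot),
      subquadratsPerQuadrat = as.integer(subquadratsPerQuadrat),
      quadratArea = as.numeric(quadratArea),
      subquadratArea = as.numeric(quadratArea) / subquadratsPerQuadrat,
      analysisLevel = analysisLevel)
}

#' Validated macrofungal survey container
#'
#' Bundles the three survey tables with the design they were recorded under:
#' long-format species observations (one row per sampling unit x species,
#' with the 1-4 individual-number code summed over sporocarp groups), the
#' per-species trait catalog, and the per-unit environment table (three
#' litterfall-layer thicknesses in cm, ordinal coarse plant-remains level
#' 1-4). Absent species/unit combinations are implicit zeros.
#'
#' Sampling-unit keys are hierarchical strings
#' \code{"forest/treatment/quadrat/subquadrat"}.
#'
#' @slot observations data.frame with columns \code{unit}, \code{species},
#'   \code{individual_number}.
#' @slot traits data.frame with columns \code{species}, \code{order},
#'   \code{trophic}, \code{attachment}, \code{sporocarp}, \code{geographic},
#'   \code{edibility}.
#' @slot environment data.frame with columns \code{unit}, \code{lay1_cm},
#'   \code{lay2_cm}, \code{lay3_cm}, \code{remains_level}.
#' @slot design a \code{SurveyDesign}.
#' @export
setClass("FungalSurvey", representation(
  observations = "data.frame",
  traits = "data.frame",
  environment = "data.frame",
  design = "SurveyDesign"
))

setValidity("FungalSurvey", function(object) {
  msgs <- character()
  obs <- object@observations
  tr <- object@traits
  env <- object@environment
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", "))
    else character()
  }
  msgs <- c(msgs,
            need(obs, c("unit", "species", "individual_number"), "observations"),
            need(tr, c("species", TRAIT_AXES), "traits"),
            need(env, c("unit", "lay1_cm", "lay2_cm", "lay3_cm", "remains_level"),
                 "environment"))
  if (length(msgs)) return(msgs)

  dup <- duplicated(obs[c("unit", "species")])
  if (any(dup)) {
    d <- obs[dup, , drop = FALSE][1, ]
    msgs <- c(msgs, sprintf(
      "duplicate (unit, species) observation: (%s, %s)", d$unit, d$species))
  }
  if (nrow(obs) && any(!is.finite(obs$individual_number) |
                       obs$individual_number < 1 |
                       obs$individual_number != round(obs$individual_number)))
    msgs <- c(msgs, "individual_number must be a positive integer")
  orphan <- setdiff(obs$species, tr$species)
  if (length(orphan))
    msgs <- c(msgs, sprintf("species without trait rows: %s",
                            paste(utils::head(orphan, 5), collapse = ", ")))
  for (ax in names(TRAIT_LEVELS)) {
    bad <- setdiff(unique(tr[[ax]]), TRAIT_LEVELS[[ax]])
    if (length(bad))
      msgs <- c(msgs, sprintf("invalid %s value(s): %s", ax,
                              paste(bad, collapse = ", ")))
  }
  if (nrow(env)) {
    if (any(env$lay1_cm < 0 | env$lay2_cm < 0 | env$lay3_cm < 0))
      msgs <- c(msgs, "litterfall thicknesses must be >= 0")
    if (any(!env$remains_level %in% 1:4))
      msgs <- c(msgs, "remains_level must be in {1,2,3,4}")
    if (anyDuplicated(env$unit))
      msgs <- c(msgs, "duplicate unit in environment table")
  }
  keys <- unique(c(obs$unit, env$unit))
  parsed <- tryCatch(parseUnitKeys(keys), error = function(e) NULL)
  if (is.null(parsed)) {
    msgs <- c(msgs, "malformed unit key(s); expected forest/treatment/quadrat/subquadrat")
  } else {
    badF <- setdiff(unique(parsed$forest), object@design@forestTypes)
    if (length(badF))
      msgs <- c(msgs, sprintf("unit keys reference unknown forest type(s): %s",
                              paste(badF, collapse = ", ")))
    badT <- setdiff(unique(parsed$treatment), object@design@treatments)
    if (length(badT))
      msgs <- c(msgs, sprintf("unit keys reference unknown treatment(s): %s",
                              paste(badT, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Spore measurement notation summary
#'
#' Holds the components of the morphometric range notation
#' \code{\{a/b/c\} (d) e-f (g) [h +/- i, j]}: values measured from \code{a}
#' spores of \code{b} sporocarps in \code{c} collections, with \code{[e, f]}
#' covering at least 90\% of the values, \code{d}/\code{g} the extremes,
#' \code{h} the mean, \code{i} the sample standard deviation and \code{j}
#' the mode.
#'
#' @slot a,b,c integer counts (spores, sporocarps, collections).
#' @slot d,e,f,g,h,i,j numeric summary components.
#' @slot grid numeric recording grid in the measurement unit (NA when
#'   summarising unitless ratios).
#' @export
setClass("NotationSummary", representation(
  a = "integer", b = "integer", c = "integer",
  d = "numeric", e = "numeric", f = "numeric", g = "numeric",
  h = "numeric", i = "numeric", j = "numeric",
  grid = "numeric"
))

setValidity("NotationSummary", function(object) {
  msgs <- character()
  if (!(object@d <= object@e + 1e-9 && object@e <= object@f + 1e-9 &&
        object@f <= object@g + 1e-9))
    msgs <- c(msgs, "require d <= e <= f <= g")
  if (object@i < 0) msgs <- c(msgs, "standard deviation must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SurveyDesign", function(object) {
  cat(sprintf(
    "SurveyDesign: %d forest type(s) x {ungrazed, grazed}; %d quadrat(s) (%g m2) x %d subquadrat(s) (%g m2); analysis level: %s\n",
    length(object@forestTypes), object@quadratsPerPlot, object@quadratArea,
    object@subquadratsPerQuadrat, object@subquadratArea, object@analysisLevel))
  cat("  forest types:", paste(object@forestTypes, collapse = ", "), "\n")
})

setMethod("show", "FungalSurvey", function(object) {
  cat(sprintf(
    "FungalSurvey: %d observation(s) of %d species over %d sampling unit(s)\n",
    nrow(object@observations), length(unique(object@observations$species)),
    length(unique(c(object@observations$unit, object@environment$unit)))))
  show(object@design)
})

setMethod("show", "NotationSummary", function(object) {
  cat(formatNotation(object), "\n")
})
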