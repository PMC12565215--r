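#' Build hierarchical sampling-unit keys
#'
#' Unit keys are strings \code{"forest/treatment/quadrat/subquadrat"}; the
#' subquadrat is the minimum recording unit.
#'
#' @param forest,treatment character vectors.
#' @param quadrat,subquadrat integer vectors.
#' @return character vector of keys.
#' @export
makeUnitKey <- function(forest, treatment, quadrat, subquadrat) {
  paste(forest, treatment, quadrat, subquadrat, sep = "/")
}

#' Parse sampling-unit keys
#'
#' @param keys character vector of \code{"forest/treatment/quadrat/subquadrat"}
#'   keys.
#' @return data.frame with columns \code{unit}, \code{forest},
#'   \code{treatment}, \code{quadrat}, \code{subquadrat}, \code{quadrat_key}
#'   (the key truncated to quadrat level, used when pooling subquadrats).
#' @export
parseUnitKeys <- function(keys) {
  parts <- strsplit(as.character(keys), "/", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    validationError(sprintf("malformed unit key(s): %s",
                            paste(utils::head(keys[bad], 5), collapse = ", ")))
  m <- do.call(rbind, parts)
  data.frame(
    unit = as.character(keys),
    forest = m[, 1], treatment = m[, 2],
    quadrat = m[, 3], subquadrat = m[, 4],
    quadrat_key = paste(m[, 1], m[, 2], m[, 3], sep = "/"),
    stringsAsFactors = FALSE
  )
}

## ---- category normalization ------------------------------------------------

# Normalize a free-form label to lower case, singular, with filler words
# ("fungi", "fungus" as a morphotype suffix, "components", "types") removed.
.normalToken <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[_]+", " ", x)
  x <- gsub("\\s+", " ", x)
  x <- sub(" (fungi|fungus)$", "", x)
  x <- sub("s$", "", x)
  x
}

# Lookup tables from normalized token -> canonical level, built once.
.traitLookup <- local({
  tabs <- lapply(TRAIT_LEVELS, function(levels) {
    tok <- .normalToken(levels)
    stats::setNames(levels, tok)
  })
  # irregulars seen in field tables
  tabs$sporocarp <- c(tabs$sporocarp, stats::setNames("ascomycete", "ascomycetes"))
  tabs$edibility <- c(tabs$edibility, stats::setNames("medicinal", "medical"))
  tabs$sporocarp <- c(tabs$sporocarp, stats::setNames("slime mold", "slime mould"))
  tabs
})

#' Normalize trait category labels
#'
#' Maps free-form labels (case, plural and "... fungi"-suffix insensitive,
#' e.g. \code{"Wood saprotrophs"}, \code{"Polyporoid fungi"},
#' \code{"Medical"}) to the canonical enumeration for an axis.
#'
#' @param x character vector of labels.
#' @param axis one of \code{"trophic"}, \code{"attachment"},
#'   \code{"sporocarp"}, \code{"geographic"}, \code{"edibility"}.
#' @return character vector of canonical levels.
#' @export
normalizeTrait <- function(x, axis) {
  axis <- match.arg(axis, names(TRAIT_LEVELS))
  lut <- .traitLookup[[axis]]
  out <- unname(lut[.normalToken(x)])
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    validationError(sprintf("invalid %s value(s): %s", axis,
                            paste(unique(x[bad]), collapse = ", ")))
  out
}

## ---- readers / writers -----------------------------------------------------

.readTable <- function(path, delim = ",") {
  if (!file.exists(path))
    validationError(sprintf("input file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8", comment.char = "")
}

.writeTable <- function(df, path, delim = ",") {
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     qmethod = "double", quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format observation table
#'
#' Expects a header with at least \code{unit}, \code{species},
#' \code{individual_number}; extra columns are preserved. Validates that each
#' (unit, species) pair occurs at most once and that individual numbers are
#' positive integers.
#'
#' @param path file path.
#' @param delim field delimiter (\code{","} or \code{"\t"}).
#' @return validated observations data.frame.
#' @export
readObservations <- function(path, delim = ",") {
  df <- .readTable(path, delim)
  validateObservations(df)
}

#' Validate an observation data.frame
#' @param df data.frame with \code{unit}, \code{species},
#'   \code{individual_number}.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateObservations <- function(df) {
  miss <- setdiff(c("unit", "species", "individual_number"), names(df))
  if (length(miss))
    validationError(sprintf("observations lack column(s): %s",
                            paste(miss, collapse = ", ")))
  dup <- duplicated(df[c("unit", "species")])
  if (any(dup)) {
    d <- unique(df[dup, c("unit", "species"), drop = FALSE])
    validationError(sprintf(
      "duplicate (unit, species) pair(s): %s",
      paste(sprintf("(%s, %s)", d$unit, d$species)[seq_len(min(5, nrow(d)))],
            collapse = "; ")))
  }
  n <- df$individual_number
  if (nrow(df) && any(!is.finite(n) | n < 1 | n != round(n)))
    validationError("individual_number must be a positive integer")
  df$individual_number <- as.integer(df$individual_number)
  parseUnitKeys(df$unit)  # key shape check
  df
}

#' Read a species trait catalog
#'
#' Columns: \code{species}, \code{order}, \code{trophic}, \code{attachment},
#' \code{sporocarp}, \code{geographic}, \code{edibility}. Category labels are
#' normalized to the canonical enumerations; unknown labels are errors naming
#' the offending value.
#'
#' @inheritParams readObservations
#' @return validated trait data.frame.
#' @export
readTraits <- function(path, delim = ",") {
  df <- .readTable(path, delim)
  validateTraits(df)
}

#' Validate and normalize a trait catalog data.frame
#' @param df data.frame with species and the six classification axes.
#' @return data.frame with normalized category labels.
#' @export
validateTraits <- function(df) {
  miss <- setdiff(c("species", TRAIT_AXES), names(df))
  if (length(miss))
    validationError(sprintf("traits lack column(s): %s",
                            paste(miss, collapse = ", ")))
  if (anyDuplicated(df$species))
    validationError(sprintf("duplicate species in trait catalog: %s",
                            df$species[duplicated(df$species)][1]))
  for (ax in names(TRAIT_LEVELS)) df[[ax]] <- normalizeTrait(df[[ax]], ax)
  df
}

#' Read a per-unit environment table
#'
#' Columns: \code{unit}, \code{lay1_cm} (undecomposed litterfall layer),
#' \code{lay2_cm} (semi-decomposed), \code{lay3_cm} (decomposed),
#' \code{remains_level} (ordinal 1-4 abundance of large plant remains).
#' A derived \code{lays_cm} total column is added.
#'
#' @inheritParams readObservations
#' @return validated environment data.frame with \code{lays_cm}.
#' @export
readEnvironment <- function(path, delim = ",") {
  df <- .readTable(path, delim)
  validateEnvironment(df)
}

#' Validate an environment data.frame
#' @param df data.frame with unit, three layer thicknesses and remains level.
#' @return validated data.frame with derived \code{lays_cm}.
#' @export
validateEnvironment <- function(df) {
  miss <- setdiff(c("unit", "lay1_cm", "lay2_cm", "lay3_cm", "remains_level"),
                  names(df))
  if (length(miss))
    validationError(sprintf("environment lacks column(s): %s",
                            paste(miss, collapse = ", ")))
  if (anyDuplicated(df$unit))
    validationError("duplicate unit in environment table")
  for (cl in c("lay1_cm", "lay2_cm", "lay3_cm"))
    if (any(!is.finite(df[[cl]]) | df[[cl]] < 0))
      validationError(sprintf("%s must be finite and >= 0", cl))
  if (any(!df$remains_level %in% 1:4))
    validationError(sprintf(
      "remains_level must be in {1,2,3,4}; offending value(s): %s",
      paste(unique(df$remains_level[!df$remains_level %in% 1:4]),
            collapse = ", ")))
  parseUnitKeys(df$unit)
  df$lays_cm <- df$lay1_cm + df$lay2_cm + df$lay3_cm
  df
}

#' @rdname readObservations
#' @param df data.frame to write.
#' @export
writeObservations <- function(df, path, delim = ",") {
  .writeTable(df, path, delim)
}

#' @rdname readTraits
#' @param df data.frame to write.
#' @export
writeTraits <- function(df, path, delim = ",") .writeTable(df, path, delim)

#' @rdname readEnvironment
#' @param df data.frame to write.
#' @export
writeEnvironment <- function(df, path, delim = ",") {
  df$lays_cm <- NULL
  .writeTable(df, path, delim)
}

#' Convert a wide species x unit abundance matrix to long observations
#'
#' @param m numeric matrix, rows = species (rownames), columns = unit keys
#'   (colnames); zero cells are dropped.
#' @return long observations data.frame.
#' @export
wideToLong <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    validationError("wide matrix needs species rownames and unit colnames")
  idx <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(
    unit = colnames(m)[idx[, 2]],
    species = rownames(m)[idx[, 1]],
    individual_number = as.integer(m[idx]),
    stringsAsFactors = FALSE
  )
  df[order(df$unit, df$species), , drop = FALSE]
}

#' Assemble a validated survey container
#'
#' @param observations long observations data.frame (or path).
#' @param traits trait catalog data.frame (or path).
#' @param environment environment data.frame (or path).
#' @param design a \code{SurveyDesign}; inferred from the unit keys when
#'   omitted.
#' @param delim delimiter used when paths are given.
#' @return a \code{FungalSurvey}.
#' @export
fungalSurvey <- function(observations, traits, environment, design = NULL,
                         delim = ",") {
  if (is.character(observations)) observations <- readObservations(observations, delim)
  else observations <- validateObservations(observations)
  if (is.character(traits)) traits <- readTraits(traits, delim)
  else traits <- validateTraits(traits)
  if (is.character(environment)) environment <- readEnvironment(environment, delim)
  else environment <- validateEnvironment(environment)
  if (is.null(design)) {
    keys <- parseUnitKeys(unique(c(observations$unit, environment$unit)))
    design <- surveyDesign(sort(unique(keys$forest)))
  }
  obj <- new("FungalSurvey", observations = observations, traits = traits,
             environment = environment, design = design)
  validObject(obj)
  obj
}

## ---- accessors -------------------------------------------------------------

#' @title Accessors for FungalSurvey components
#' @param object a \code{FungalSurvey}.
#' @return the requested component.
#' @name survey-accessors
NULL

#' @rdname survey-accessors
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))
#' @rdname survey-accessors
#' @export
setMethod("observations", "FungalSurvey", function(object) object@observations)

#' @rdname survey-accessors
#' @export
setGeneric("traitCatalog", function(object) standardGeneric("traitCatalog"))
#' @rdname survey-accessors
#' @export
setMethod("traitCatalog", "FungalSurvey", function(object) object@traits)

#' @rdname survey-accessors
#' @export
setGeneric("environmentTable", function(object) standardGeneric("environmentTable"))
#' @rdname survey-accessors
#' @export
setMethod("environmentTable", "FungalSurvey", function(object) {
  env <- object@environment
  if (!"lays_cm" %in% names(env))
    env$lays_cm <- env$lay1_cm + env$lay2_cm + env$lay3_cm
  env
})

#' @rdname survey-accessors
#' @export
setGeneric("surveyDesignOf", function(object) standardGeneric("surveyDesignOf"))
#' @rdname survey-accessors
#' @export
setMethod("surveyDesignOf", "FungalSurvey", function(object) object@design)
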