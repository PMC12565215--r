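#' Grazed-versus-ungrazed comparison table for one set of variables
#'
#' Builds the comparison rows (medians, U, p, Cliff's delta, conclusion)
#' for each stratum: every forest type separately and a pooled "General"
#' stratum combining all forest types within treatment.
#'
#' @param survey a \code{\link{FungalSurvey}}.
#' @param what \code{"diversity"} (Div/Eve/Ric per sampling unit) or
#'   \code{"environment"} (the three litterfall layers, their total, and
#'   the plant-remains level).
#' @param level analysis level passed to \code{\link{aggregateCounts}}.
#' @param alpha significance level.
#' @return data.frame of comparison rows.
#' @export
compareStrata <- function(survey, what = c("diversity", "environment"),
                          level = c("subquadrat", "quadrat"), alpha = 0.05) {
  what <- match.arg(what)
  level <- match.arg(level)
  design <- survey@design
  strata <- c(as.list(design@forestTypes), list(design@forestTypes))
  names(strata) <- c(design@forestTypes, "General")

  getValues <- function(forest, treatment) {
    if (what == "diversity") {
      agg <- aggregateCounts(survey, forest = forest, treatment = treatment,
                             level = level)
      ud <- unitDiversity(agg)
      # units with no fungal record at all contribute nothing here; units
      # with a single species contribute Div = Ric = 0 and undefined Eve
      list(
        `Diversity index` = ud$Div,
        `Evenness index` = ud$Eve[!is.na(ud$Eve)],
        `Richness index` = ud$Ric
      )
    } else {
      env <- environmentTable(survey)
      keys <- parseUnitKeys(env$unit)
      sel <- keys$forest %in% forest & keys$treatment == treatment
      e <- env[sel, , drop = FALSE]
      if (level == "quadrat") {
        qk <- keys$quadrat_key[sel]
        e <- do.call(rbind, lapply(split(e, qk), function(p) data.frame(
          lay1_cm = mean(p$lay1_cm), lay2_cm = mean(p$lay2_cm),
          lay3_cm = mean(p$lay3_cm), lays_cm = mean(p$lays_cm),
          remains_level = stats::median(p$remains_level)
        )))
      }
      list(
        `Undecomposed layer` = e$lay1_cm,
        `Semi-decomposed layer` = e$lay2_cm,
        `Decomposed layer` = e$lay3_cm,
        `All litterfall layers` = e$lays_cm,
        `Large plant remains` = e$remains_level
      )
    }
  }

  rows <- list()
  for (sn in names(strata)) {
    xs <- getValues(strata[[sn]], "ungrazed")
    ys <- getValues(strata[[sn]], "grazed")
    for (v in names(xs)) {
      if (length(xs[[v]]) == 0 || length(ys[[v]]) == 0) next
      cmp <- classifyChange(xs[[v]], ys[[v]], alpha)
      rows[[length(rows) + 1]] <- comparisonRow(sn, v, cmp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dominance tables for every axis and stratum
#'
#' @param survey a \code{\link{FungalSurvey}}.
#' @param axes classification axes; default all seven (species plus the six
#'   trait axes).
#' @param k top groups to keep per table.
#' @param level analysis level.
#' @return data.frame with \code{stratum}, \code{treatment}, \code{axis}
#'   prepended to the \code{\link{dominanceTable}} columns.
#' @export
dominanceByAxis <- function(survey,
                            axes = c("species", TRAIT_AXES),
                            k = 3, level = c("subquadrat", "quadrat")) {
  level <- match.arg(level)
  design <- survey@design
  traits <- survey@traits
  strata <- c(as.list(design@forestTypes), list(design@forestTypes))
  names(strata) <- c(design@forestTypes, "General")
  rows <- list()
  for (sn in names(strata)) for (tr in c("ungrazed", "grazed")) {
    agg <- aggregateCounts(survey, forest = strata[[sn]], treatment = tr,
                           level = level)
    if (agg$N == 0) next
    for (ax in axes) {
      grouping <- if (ax == "species") NULL
                  else stats::setNames(traits[[ax]], traits$species)
      tab <- dominanceTable(agg, grouping, k = k)
      tab <- cbind(stratum = sn, treatment = tr, axis = ax, tab,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinations for the standard stratifications
#'
#' Runs the correlation PCA per forest type (both treatments pooled) at
#' subquadrat level, for all forest types together at subquadrat level, and
#' for all forest types together at quadrat level.
#'
#' @param survey a \code{\link{FungalSurvey}}.
#' @return named list of \code{\link{surveyPca}} results (with the feature
#'   matrix attached as \code{matrix}).
#' @export
ordinationBundle <- function(survey) {
  design <- survey@design
  env <- environmentTable(survey)
  runOne <- function(forest, level) {
    agg <- aggregateCounts(survey, forest = forest, level = level)
    div <- unitDiversity(agg)
    keys <- parseUnitKeys(env$unit)
    sel <- keys$forest %in% forest
    e <- env[sel, , drop = FALSE]
    if (level == "quadrat") {
      qk <- keys$quadrat_key[sel]
      parts <- split(e, qk)
      e <- do.call(rbind, lapply(names(parts), function(u) {
        p <- parts[[u]]
        data.frame(
          unit = u, lay1_cm = mean(p$lay1_cm), lay2_cm = mean(p$lay2_cm),
          lay3_cm = mean(p$lay3_cm), lays_cm = mean(p$lays_cm),
          remains_level = stats::median(p$remains_level),
          stringsAsFactors = FALSE
        )
      }))
    }
    # restrict to units with fungal records (diversity defined)
    e <- e[e$unit %in% div$unit, , drop = FALSE]
    div <- div[div$unit %in% e$unit, , drop = FALSE]
    m <- suppressWarnings(assembleMatrix(div, e))
    m2 <- dropZeroVariance(m)
    res <- surveyPca(m2)
    res$matrix <- m2
    res$correlations <- correlationSummary(m2)
    res
  }
  out <- lapply(design@forestTypes, function(f) runOne(f, "subquadrat"))
  names(out) <- design@forestTypes
  out$integrated_subquadrat <- runOne(design@forestTypes, "subquadrat")
  out$integrated_quadrat <- runOne(design@forestTypes, "quadrat")
  out
}

#' Run the full survey analysis
#'
#' Orchestrates the whole pipeline on a validated survey: species-set
#' partition, diversity and environment comparison tables, dominance tables
#' over all axes, and the ordination bundle. Deterministic given its input.
#'
#' @param survey a \code{\link{FungalSurvey}}.
#' @param level analysis level for the comparison and dominance tables.
#' @param alpha significance level.
#' @param k top groups per dominance table.
#' @return list of class \code{reportBundle} with elements \code{venn},
#'   \code{diversityComparison}, \code{environmentComparison},
#'   \code{dominance}, \code{ordination}, \code{log}.
#' @export
runFullAnalysis <- function(survey, level = c("subquadrat", "quadrat"),
                            alpha = 0.05, k = 3) {
  level <- match.arg(level)
  obs <- survey@observations
  keys <- parseUnitKeys(obs$unit)
  venn <- vennPartition(obs$species[keys$treatment == "grazed"],
                        obs$species[keys$treatment == "ungrazed"])
  bundle <- list(
    venn = venn,
    diversityComparison = compareStrata(survey, "diversity", level, alpha),
    environmentComparison = compareStrata(survey, "environment", level, alpha),
    dominance = dominanceByAxis(survey, k = k, level = level),
    ordination = ordinationBundle(survey),
    log = list(
      level = level, alpha = alpha, k = k,
      nObservations = nrow(obs),
      nSpecies = length(unique(obs$species)),
      digest = sum(as.integer(charToRaw(paste(
        utils::capture.output(utils::str(obs)), collapse = ""))))
    )
  )
  class(bundle) <- "reportBundle"
  bundle
}

#' Write a report bundle to CSV/markdown files
#'
#' @param bundle result of \code{\link{runFullAnalysis}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    diversity = file.path(dir, "diversity_comparison.csv"),
    environment = file.path(dir, "environment_comparison.csv"),
    dominance = file.path(dir, "dominance_tables.csv"),
    venn = file.path(dir, "venn_summary.csv")
  )
  .writeTable(bundle$diversityComparison, paths["diversity"])
  .writeTable(bundle$environmentComparison, paths["environment"])
  .writeTable(bundle$dominance, paths["dominance"])
  v <- bundle$venn
  .writeTable(data.frame(
    shared = v$shared, unique_grazed = v$uniqueGrazed,
    unique_ungrazed = v$uniqueUngrazed, total = v$total,
    n_grazed = v$nGrazed, n_ungrazed = v$nUngrazed
  ), paths["venn"])
  for (nm in names(bundle$ordination)) {
    res <- bundle$ordination[[nm]]
    p1 <- file.path(dir, sprintf("pca_%s_loadings.csv", nm))
    p2 <- file.path(dir, sprintf("pca_%s_explained.csv", nm))
    .writeTable(data.frame(variable = rownames(res$loadings),
                           res$loadings, check.names = FALSE), p1)
    .writeTable(data.frame(component = seq_along(res$explained),
                           explained = res$explained), p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
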