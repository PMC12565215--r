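#' Assemble the diversity-environment feature matrix
#'
#' Joins per-unit diversity indices with the per-unit environment table
#' into the 8-column matrix used for ordination: Div, Eve, Ric, Lay1, Lay2,
#' Lay3, Lays, Rem. Units present in only one input are an error (named in
#' the message). Units whose evenness is undefined (a single species) have
#' Eve imputed as 0 with a warning; \code{naAction = "drop"} removes those
#' rows instead.
#'
#' @param div per-unit diversity data.frame from \code{\link{unitDiversity}}.
#' @param env environment data.frame (validated; \code{lays_cm} derived if
#'   absent).
#' @param naAction \code{"impute"} (default) or \code{"drop"} for undefined
#'   Eve.
#' @return numeric matrix (rownames = unit keys) with attributes
#'   \code{imputedEve} (unit keys imputed) and \code{dropped}.
#' @export
assembleMatrix <- function(div, env, naAction = c("impute", "drop")) {
  naAction <- match.arg(naAction)
  if (!"lays_cm" %in% names(env))
    env$lays_cm <- env$lay1_cm + env$lay2_cm + env$lay3_cm
  onlyDiv <- setdiff(div$unit, env$unit)
  onlyEnv <- setdiff(env$unit, div$unit)
  if (length(onlyDiv) || length(onlyEnv))
    validationError(sprintf(
      "unit keys do not align; missing environment for [%s], missing diversity for [%s]",
      paste(onlyDiv, collapse = ", "), paste(onlyEnv, collapse = ", ")))
  m <- merge(div, env, by = "unit")
  imputed <- character(0); dropped <- character(0)
  und <- is.na(m$Eve)
  if (any(und)) {
    if (naAction == "impute") {
      imputed <- m$unit[und]
      warning(sprintf("Eve undefined (S <= 1) for %d unit(s); imputed as 0",
                      sum(und)))
      m$Eve[und] <- 0
    } else {
      dropped <- m$unit[und]
      m <- m[!und, , drop = FALSE]
    }
  }
  out <- as.matrix(data.frame(
    Div = m$Div, Eve = m$Eve, Ric = m$Ric,
    Lay1 = m$lay1_cm, Lay2 = m$lay2_cm, Lay3 = m$lay3_cm,
    Lays = m$lays_cm, Rem = as.numeric(m$remains_level)
  ))
  rownames(out) <- m$unit
  attr(out, "imputedEve") <- imputed
  attr(out, "dropped") <- dropped
  out
}

#' Drop zero-variance columns before ordination
#'
#' Columns with zero sample variance carry no correlation information and
#' cannot be standardised; they are removed and reported (e.g. a decomposed
#' litterfall layer that is 0 in every plantation unit).
#'
#' @param m numeric matrix with >= 2 rows.
#' @return the reduced matrix, with attribute \code{excluded} naming the
#'   removed columns.
#' @export
dropZeroVariance <- function(m) {
  if (nrow(m) < 2)
    validationError("need at least 2 rows to assess variance")
  v <- apply(m, 2, stats::var)
  zero <- v <= 0 | !is.finite(v)
  if (all(zero))
    validationError("all columns have zero variance")
  out <- m[, !zero, drop = FALSE]
  attr(out, "excluded") <- colnames(m)[zero]
  attr(out, "imputedEve") <- attr(m, "imputedEve")
  out
}

#' Correlation (standardised) principal component analysis
#'
#' Standardises each column to zero mean and unit variance and
#' eigendecomposes the correlation structure (via \code{stats::prcomp}).
#' Component signs are fixed deterministically: each loading vector's
#' largest-magnitude entry is made positive.
#'
#' @param m numeric matrix from \code{\link{assembleMatrix}} /
#'   \code{\link{dropZeroVariance}}; no zero-variance columns allowed.
#' @return list with \code{loadings} (variables x components),
#'   \code{scores} (units x components), \code{explained} (variance
#'   fractions), \code{excluded} (propagated from
#'   \code{\link{dropZeroVariance}}).
#' @export
surveyPca <- function(m) {
  if (nrow(m) < 2)
    validationError("need at least 2 rows for PCA")
  v <- apply(m, 2, stats::var)
  if (any(v <= 0 | !is.finite(v)))
    validationError(sprintf(
      "zero-variance column(s) must be dropped before PCA: %s",
      paste(colnames(m)[v <= 0 | !is.finite(v)], collapse = ", ")))
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  sco <- pc$x
  for (jj in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, jj]))
    if (rot[top, jj] < 0) {
      rot[, jj] <- -rot[, jj]
      sco[, jj] <- -sco[, jj]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = rot, scores = sco, explained = expl,
       excluded = attr(m, "excluded") %||% character(0))
}

#' Pairwise correlation summary
#'
#' Pearson correlations between all column pairs with two-sided p-values
#' and the qualitative labels used when reading ordination output:
#' direction (positive/negative) crossed with strength (significant at
#' alpha, else slight).
#'
#' @param m numeric matrix.
#' @param alpha significance level (default 0.05).
#' @return data.frame with \code{var1}, \code{var2}, \code{r}, \code{p},
#'   \code{label}.
#' @export
correlationSummary <- function(m, alpha = 0.05) {
  cols <- colnames(m)
  pairs <- utils::combn(cols, 2)
  rows <- apply(pairs, 2, function(pr) {
    ct <- stats::cor.test(m[, pr[1]], m[, pr[2]], method = "pearson")
    r <- unname(ct$estimate)
    data.frame(
      var1 = pr[1], var2 = pr[2], r = r, p = ct$p.value,
      label = paste(if (r >= 0) "positive" else "negative",
                    if (ct$p.value < alpha) "significant" else "slight"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
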