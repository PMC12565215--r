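#' Cluster conspecific sporocarps into survey individuals
#'
#' Implements the distance-based individual-number coding used at recording
#' time: conspecific sporocarps within one sampling unit are chained into a
#' group by single linkage whenever neighbours are at most \code{separation}
#' (2 m) apart; sporocarps farther than 2 m from every member of a group
#' count as another individual. Each group receives a code describing how
#' tight it is, via its largest within-group nearest-neighbour gap g:
#' singleton -> 1; g <= 0.5 m -> 2; g <= 1 m -> 3; g <= 2 m -> 4. All
#' thresholds are inclusive; the split between groups is strict (> 2 m).
#'
#' @param x,y numeric vectors of sporocarp coordinates in meters, local to
#'   one subquadrat, for a single species.
#' @param separation linkage cut in meters (default 2).
#' @return data.frame with one row per group: \code{cluster}, \code{members},
#'   \code{max_gap} (largest nearest-neighbour distance inside the group, 0
#'   for singletons), \code{code}.
#' @examples
#' clusterIndividuals(c(0, 0.4), c(0, 0))        # one group, code 2
#' clusterIndividuals(c(0, 2.5), c(0, 0))        # two singletons
#' @export
clusterIndividuals <- function(x, y, separation = 2) {
  if (length(x) == 0)
    validationError("no sporocarp points supplied")
  if (length(x) != length(y) || any(!is.finite(x)) || any(!is.finite(y)))
    validationError("x and y must be finite coordinate vectors of equal length")
  npt <- length(x)
  if (npt == 1L) {
    return(data.frame(cluster = 1L, members = 1L, max_gap = 0, code = 1L))
  }
  d <- stats::dist(cbind(x, y))
  hc <- stats::hclust(d, method = "single")
  cl <- stats::cutree(hc, h = separation)
  dm <- as.matrix(d)
  out <- lapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    if (length(idx) == 1L)
      return(data.frame(cluster = k, members = 1L, max_gap = 0, code = 1L))
    sub <- dm[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    g <- max(apply(sub, 1, min))  # largest nearest-neighbour gap
    code <- if (g <= 0.5) 2L else if (g <= 1) 3L else 4L
    data.frame(cluster = k, members = length(idx), max_gap = g, code = code)
  })
  do.call(rbind, out)
}

#' Individual number of one species in one sampling unit
#'
#' The recorded individual number is the sum of the group codes from
#' \code{\link{clusterIndividuals}} (default), or optionally the code of the
#' single largest group.
#'
#' @inheritParams clusterIndividuals
#' @param combine \code{"sum"} (default) or \code{"max"}.
#' @return positive integer.
#' @export
individualNumber <- function(x, y, separation = 2, combine = c("sum", "max")) {
  combine <- match.arg(combine)
  codes <- clusterIndividuals(x, y, separation)$code
  if (combine == "sum") sum(codes) else max(codes)
}

#' Convert sporocarp coordinate records to observation rows
#'
#' @param points data.frame with columns \code{unit}, \code{species},
#'   \code{x_m}, \code{y_m} (one row per sporocarp).
#' @param separation linkage cut in meters.
#' @param combine code combination rule, see \code{\link{individualNumber}}.
#' @return observations data.frame (\code{unit}, \code{species},
#'   \code{individual_number}).
#' @export
pointsToObservations <- function(points, separation = 2,
                                 combine = c("sum", "max")) {
  combine <- match.arg(combine)
  miss <- setdiff(c("unit", "species", "x_m", "y_m"), names(points))
  if (length(miss))
    validationError(sprintf("points table lacks column(s): %s",
                            paste(miss, collapse = ", ")))
  parts <- split(points, list(points$unit, points$species), drop = TRUE)
  rows <- lapply(parts, function(p) data.frame(
    unit = p$unit[1], species = p$species[1],
    individual_number = individualNumber(p$x_m, p$y_m, separation, combine),
    stringsAsFactors = FALSE
  ))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$unit, df$species), , drop = FALSE]
}
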