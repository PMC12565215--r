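#' Dominance index over a classification axis
#'
#' For a group j of species (a single species, or all species sharing a
#' trait value), the dominance index averages the group's normalised
#' relative frequency (occupancy share) and relative density (abundance
#' share):
#' \deqn{Dom_j = \{[(q_j/Q) / \sum_i (q_i/Q)] + n_j/N\}/2 \in [0, 100\%]}
#' with \eqn{q_j = \sum_{i \in j} q_i} and \eqn{n_j = \sum_{i \in j} n_i}
#' under the additive occupancy convention (the default), which makes every
#' complete partition sum to exactly 100\%. The literal convention
#' ("units where any member occurs") is available via
#' \code{occupancy = "literal"}; it requires \code{perUnit} data and does
#' not guarantee the 100\% partition sum.
#'
#' @param agg stratum aggregate from \code{\link{aggregateCounts}} (needs
#'   \code{n}, \code{q}; \code{perUnit} for the literal convention).
#' @param grouping named character vector mapping species to group labels
#'   on the chosen axis; \code{NULL} treats each species as its own group.
#' @param occupancy \code{"additive"} (default) or \code{"literal"}.
#' @return named numeric vector of dominance percentages, one per group.
#' @examples
#' agg <- list(n = c(A = 3, B = 1), q = c(A = 2, B = 1), N = 4, Q = 2)
#' dominanceIndex(agg)  # A = 70.83..., B = 29.16...
#' @export
dominanceIndex <- function(agg, grouping = NULL,
                           occupancy = c("additive", "literal")) {
  occupancy <- match.arg(occupancy)
  n <- agg$n; q <- agg$q
  if (length(n) == 0 || sum(n) == 0 || sum(q) == 0)
    validationError("stratum has no individuals; dominance undefined")
  species <- names(n)
  if (is.null(grouping)) grouping <- stats::setNames(species, species)
  miss <- setdiff(species, names(grouping))
  if (length(miss))
    validationError(sprintf("species without group assignment: %s",
                            paste(utils::head(miss, 5), collapse = ", ")))
  grp <- factor(grouping[species])
  nj <- tapply(as.numeric(n), grp, sum)
  if (occupancy == "additive") {
    qj <- tapply(as.numeric(q), grp, sum)
    freq <- qj / sum(q)
  } else {
    if (is.null(agg$perUnit))
      validationError("literal occupancy needs per-unit presence data")
    qj <- vapply(levels(grp), function(g) {
      members <- species[grp == g]
      sum(vapply(agg$perUnit, function(v) any(names(v) %in% members), logical(1)))
    }, numeric(1))
    freq <- (qj / agg$Q) / sum(q / agg$Q)
  }
  dom <- (freq + nj / sum(n)) / 2 * 100
  stats::setNames(as.numeric(dom), levels(grp))
}

#' Ranked dominance table
#'
#' Sorts groups by dominance and keeps the top \code{k}; exact ties share a
#' rank (and may extend the table past \code{k} when the last kept rank is
#' tied). Ranking uses unrounded values; percentages are rounded to 2
#' decimals only for display.
#'
#' @inheritParams dominanceIndex
#' @param k number of top groups to keep; \code{Inf} keeps all.
#' @return data.frame with \code{rank}, \code{group}, \code{dominance_pct}
#'   (unrounded), \code{dominance_display} (2 decimals), \code{tied} flag.
#' @export
dominanceTable <- function(agg, grouping = NULL, k = 3,
                           occupancy = c("additive", "literal")) {
  dom <- dominanceIndex(agg, grouping, occupancy)
  ord <- order(-dom, names(dom))
  dom <- dom[ord]
  # competition ranking on exact values
  rnk <- rep(NA_integer_, length(dom))
  r <- 1L
  i <- 1L
  while (i <= length(dom)) {
    tieSet <- which(abs(dom - dom[i]) < 1e-12)
    tieSet <- tieSet[tieSet >= i]
    rnk[tieSet] <- r
    i <- max(tieSet) + 1L
    r <- r + length(tieSet)
  }
  keep <- if (is.finite(k)) rnk <= k | rnk <= max(rnk[seq_len(min(k, length(rnk)))])
          else rep(TRUE, length(dom))
  tied <- rnk %in% rnk[duplicated(rnk)]
  out <- data.frame(
    rank = rnk, group = names(dom), dominance_pct = as.numeric(dom),
    dominance_display = sprintf("%.2f%%", roundHalfUp(dom, 2)),
    tied = tied, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
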