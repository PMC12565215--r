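#' Simpson's index of diversity
#'
#' \eqn{Div = 1 - \sum_i (n_i/N)^2 \in [0, 1]}: the probability that two
#' randomly selected individuals belong to different species.
#'
#' @param n named (or plain) vector of per-species individual numbers;
#'   zeros are ignored.
#' @return number in [0, 1].
#' @examples
#' simpsonDiv(c(A = 3, B = 1))  # 0.375
#' @export
simpsonDiv <- function(n) {
  n <- .checkAbundance(n)
  p <- n / sum(n)
  1 - sum(p^2)
}

#' Pielou's index of evenness
#'
#' \eqn{Eve = -\sum_i (n_i/N) \ln(n_i/N) / \ln S \in [0, 1]}: Shannon
#' entropy normalised by its maximum. Undefined (\code{NA}) when the unit
#' holds a single species, since \eqn{\ln 1 = 0}.
#'
#' @inheritParams simpsonDiv
#' @return number in [0, 1], or \code{NA} for S <= 1.
#' @examples
#' pielouEve(c(A = 4, B = 4))  # 1
#' @export
pielouEve <- function(n) {
  n <- .checkAbundance(n)
  S <- length(n)
  if (S <= 1L) return(NA_real_)
  p <- n / sum(n)
  -sum(p * log(p)) / log(S)
}

#' Margalef's index of richness
#'
#' \eqn{Ric = (S - 1)/\ln N \ge 0}: species count per unit (log) number of
#' individuals. Defined as 0 when N = 1 (which forces S = 1), consistent
#' with the S = 1 limit.
#'
#' @inheritParams simpsonDiv
#' @return number >= 0.
#' @examples
#' margalefRic(c(A = 3, B = 1))  # 1/log(4)
#' @export
margalefRic <- function(n) {
  n <- .checkAbundance(n)
  N <- sum(n)
  if (N <= 1) return(0)
  (length(n) - 1) / log(N)
}

.checkAbundance <- function(n) {
  if (length(n) == 0)
    validationError("empty abundance vector")
  if (any(!is.finite(n) | n < 0))
    validationError("abundances must be finite and non-negative")
  n <- n[n > 0]
  if (length(n) == 0)
    validationError("abundance vector has no positive entries")
  n
}

#' Diversity profile of an abundance vector
#'
#' @inheritParams simpsonDiv
#' @return named list with \code{Div}, \code{Eve}, \code{Ric}, \code{N},
#'   \code{S}.
#' @export
diversityProfile <- function(n) {
  nn <- .checkAbundance(n)
  list(Div = simpsonDiv(nn), Eve = pielouEve(nn), Ric = margalefRic(nn),
       N = sum(nn), S = length(nn))
}

#' Per-unit diversity table for a stratum
#'
#' Computes Div/Eve/Ric for every sampling unit of an aggregated stratum
#' (see \code{\link{aggregateCounts}}). Units without any fungal record get
#' no row.
#'
#' @param agg result of \code{\link{aggregateCounts}}.
#' @return data.frame with columns \code{unit}, \code{Div}, \code{Eve},
#'   \code{Ric}, \code{N}, \code{S}; Eve is \code{NA} where S <= 1.
#' @export
unitDiversity <- function(agg) {
  rows <- lapply(names(agg$perUnit), function(u) {
    v <- agg$perUnit[[u]]
    if (length(v) == 0 || sum(v) == 0) return(NULL)
    p <- diversityProfile(v)
    data.frame(unit = u, Div = p$Div, Eve = p$Eve, Ric = p$Ric,
               N = p$N, S = p$S, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit = character(0), Div = numeric(0), Eve = numeric(0),
                      Ric = numeric(0), N = integer(0), S = integer(0))
  rownames(out) <- NULL
  out
}
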