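#' Mann-Whitney U test
#'
#' Computes both U statistics with midranks for ties. \code{u1} counts pairs
#' where \code{x} exceeds \code{y}, ties contributing one half;
#' \code{u2 = n1*n2 - u1}. The two-sided p-value uses the exact null
#' distribution when the pooled sample is tie-free and \code{n1 + n2 <= 25},
#' and otherwise a normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param x,y numeric samples (x = ungrazed, y = grazed in the survey
#'   context).
#' @return list with \code{u1}, \code{u2}, \code{uReport = min(u1, u2)},
#'   \code{p}, \code{n1}, \code{n2}, \code{method} ("exact" or "normal").
#' @examples
#' mannWhitney(c(1, 3), c(2, 4))
#' @export
mannWhitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    validationError("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))   # midranks
  R1 <- sum(r[seq_len(n1)])
  u1 <- R1 - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)

  if (!hasTies && n1 + n2 <= 25) {
    method <- "exact"
    mu <- n1 * n2 / 2
    p <- if (u1 <= mu) 2 * stats::pwilcox(u1, n1, n2)
         else 2 * (1 - stats::pwilcox(u1 - 1, n1, n2))
    p <- min(1, p)
  } else {
    method <- "normal"
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tieAdj <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u1 - mu
      cc <- sign(z) * 0.5
      z <- (z - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(u1 = u1, u2 = u2, uReport = min(u1, u2), p = p,
       n1 = n1, n2 = n2, method = method)
}

#' Cliff's delta from a U statistic
#'
#' \eqn{\delta = 2U/(n_1 n_2) - 1 \in [-1, 1]}. When U is the smaller of
#' the two U statistics (the reporting convention here), the result is
#' always <= 0 and the direction of change is carried separately by
#' \code{\link{classifyChange}}.
#'
#' @param u U statistic.
#' @param n1,n2 group sizes.
#' @return Cliff's delta.
#' @examples
#' cliffsDeltaFromU(48, 12, 12)  # -1/3
#' @export
cliffsDeltaFromU <- function(u, n1, n2) {
  if (n1 < 1 || n2 < 1)
    validationError("group sizes must be positive")
  if (u < 0 || u > n1 * n2)
    validationError("U must lie in [0, n1*n2]")
  (2 * u) / (n1 * n2) - 1
}

#' Signed Cliff's delta by pair counting
#'
#' \eqn{\delta_s = (\#\{x > y\} - \#\{x < y\})/(n_1 n_2) \in [-1, 1]}; its
#' magnitude equals that of the delta derived from the reported U whenever
#' ties contribute one half to U.
#'
#' @inheritParams mannWhitney
#' @return number in [-1, 1].
#' @export
cliffsDeltaSigned <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    validationError("both samples must be non-empty")
  # rank-based: #(x>y) + 0.5*ties = u1, #(x<y) + 0.5*ties = u2
  mw <- mannWhitney(x, y)
  (mw$u1 - mw$u2) / (mw$n1 * mw$n2)
}

#' Effect-magnitude band of a Cliff's delta
#'
#' Bands: negligible |d| < 0.147; minor 0.147 <= |d| < 0.33; moderate
#' 0.33 <= |d| < 0.474; large |d| >= 0.474.
#'
#' @param delta Cliff's delta (sign ignored).
#' @return character scalar/vector: \code{"negligible"}, \code{"minor"},
#'   \code{"moderate"} or \code{"large"}.
#' @examples
#' magnitudeClass(-0.333)  # moderate
#' @export
magnitudeClass <- function(delta) {
  a <- abs(delta)
  if (any(a > 1 + 1e-12))
    validationError("|delta| must be <= 1")
  out <- character(length(a))
  out[a < 0.147] <- "negligible"
  out[a >= 0.147 & a < 0.33] <- "minor"
  out[a >= 0.33 & a < 0.474] <- "moderate"
  out[a >= 0.474] <- "large"
  out
}

#' Grazed-versus-ungrazed comparison with conclusion code
#'
#' Runs the Mann-Whitney test, derives Cliff's delta from the reported
#' (smaller) U, bands its magnitude and renders the conclusion code used in
#' the comparison tables: a direction arrow (sign of the grazed-minus-
#' ungrazed median difference; on an exact median tie, the sign of the
#' mean-rank difference; \code{"|"} only when both vanish), a \code{*} when
#' p < alpha, and an effect symbol \code{-}/\code{+}/\code{++}/\code{+++}.
#'
#' @param xUngrazed,yGrazed numeric samples.
#' @param alpha significance level (default 0.05).
#' @return list with \code{medianUngrazed}, \code{medianGrazed}, \code{u1},
#'   \code{u2}, \code{uReport}, \code{p}, \code{delta} (from the reported U,
#'   <= 0), \code{deltaSigned}, \code{magnitude}, \code{direction},
#'   \code{significant}, \code{conclusion}.
#' @examples
#' classifyChange(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
classifyChange <- function(xUngrazed, yGrazed, alpha = 0.05) {
  mw <- mannWhitney(xUngrazed, yGrazed)
  delta <- cliffsDeltaFromU(mw$uReport, mw$n1, mw$n2)
  deltaSigned <- (mw$u1 - mw$u2) / (mw$n1 * mw$n2)
  mU <- stats::median(xUngrazed)
  mG <- stats::median(yGrazed)
  dMed <- mG - mU
  if (dMed > 0) direction <- SYM_UP
  else if (dMed < 0) direction <- SYM_DOWN
  else {
    # medians tie exactly: fall back on the mean-rank difference
    r <- rank(c(xUngrazed, yGrazed))
    dRank <- mean(r[-seq_len(mw$n1)]) - mean(r[seq_len(mw$n1)])
    direction <- if (dRank > 0) SYM_UP else if (dRank < 0) SYM_DOWN else SYM_FLAT
  }
  magnitude <- magnitudeClass(delta)
  significant <- mw$p < alpha
  conclusion <- paste(c(direction, if (significant) "*",
                        EFFECT_SYMBOLS[[magnitude]]), collapse = " ")
  list(medianUngrazed = mU, medianGrazed = mG,
       u1 = mw$u1, u2 = mw$u2, uReport = mw$uReport, p = mw$p,
       delta = delta, deltaSigned = deltaSigned,
       magnitude = magnitude, direction = direction,
       significant = significant, conclusion = conclusion)
}

#' Render a comparison as a report row
#'
#' @param stratum,variable labels for the row.
#' @param cmp result of \code{\link{classifyChange}}.
#' @return one-row data.frame mirroring the comparison-table layout
#'   (medians, U, p, delta, conclusion), with delta shown at 3 decimals
#'   (4 kept when the 3-decimal rounding is ambiguous).
#' @export
comparisonRow <- function(stratum, variable, cmp) {
  d3 <- roundHalfUp(cmp$delta, 3)
  deltaText <- if (abs(abs(cmp$delta * 1000) %% 1 - 0.5) < 1e-9)
    formatC(cmp$delta, format = "f", digits = 4)
  else formatC(d3, format = "f", digits = 3)
  data.frame(
    stratum = stratum, variable = variable,
    median_ungrazed = cmp$medianUngrazed, median_grazed = cmp$medianGrazed,
    U = roundHalfUp(cmp$uReport, 1), p = roundHalfUp(cmp$p, 3),
    delta = d3, delta_text = deltaText,
    conclusion = cmp$conclusion, stringsAsFactors = FALSE
  )
}
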