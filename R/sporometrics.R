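#' Summarise spore measurements in range notation
#'
#' Builds the components of the morphometric notation
#' \code{\{a/b/c\} (d) e-f (g) [h +/- i, j]}. The main interval [e, f] is
#' the symmetric trimmed range covering at least \code{coverage} of the
#' values, snapped outward to the recording grid and then shrunk grid-step
#' by grid-step from each end while coverage still holds (so each bound is
#' grid-minimal); d and g are the raw extremes; h is the arithmetic mean
#' and i the sample (n-1) standard deviation, both at 2 decimals; j is the
#' most frequent grid value, the smallest on ties.
#'
#' @param values numeric measurements (micrometers), length >= 2.
#' @param nSporocarps,nCollections counts b and c of the notation
#'   (default 1 each).
#' @param coverage minimum fraction of values inside [e, f] (default 0.9).
#' @param grid recording grid (default 0.5 um); \code{NA} disables snapping
#'   and reports bounds and mode at 2 decimals (used for the unitless shape
#'   ratio).
#' @return a \code{\link{NotationSummary}}.
#' @examples
#' summarizeMeasurements(rep(c(3.5, 4, 4.5, 5), c(10, 15, 10, 5)),
#'                       nSporocarps = 2, nCollections = 2)
#' @export
summarizeMeasurements <- function(values, nSporocarps = 1L, nCollections = 1L,
                                  coverage = 0.9, grid = 0.5) {
  if (length(values) < 2)
    validationError("need at least 2 measurements")
  if (any(!is.finite(values) | values <= 0))
    validationError("measurements must be finite and positive")
  x <- sort(values)
  n <- length(x)
  step <- if (is.na(grid)) 0.01 else grid
  snapLo <- function(v) floor(v / step + 1e-9) * step
  snapHi <- function(v) ceiling(v / step - 1e-9) * step

  needed <- ceiling(coverage * n - 1e-9)
  t <- floor((n - needed) / 2)          # symmetric trim per side
  e <- snapLo(x[t + 1])
  f <- snapHi(x[n - t])
  covered <- function(e, f) sum(x >= e - 1e-9 & x <= f + 1e-9) >= needed
  while (e + step <= f + 1e-9 && covered(e + step, f)) e <- e + step
  while (f - step >= e - 1e-9 && covered(e, f - step)) f <- f - step

  gridVals <- roundHalfUp(x / step) * step
  tab <- table(gridVals)
  j <- min(as.numeric(names(tab)[tab == max(tab)]))

  new("NotationSummary",
      a = as.integer(n), b = as.integer(nSporocarps), c = as.integer(nCollections),
      d = min(snapLo(min(x)), e), e = e, f = f, g = max(snapHi(max(x)), f),
      h = roundHalfUp(mean(x), 2), i = roundHalfUp(stats::sd(x), 2),
      j = roundHalfUp(j, 2), grid = as.numeric(grid))
}

.fmtBound <- function(v, grid) {
  digits <- if (is.na(grid)) 2L else max(0L, nchar(sub("^[^.]*\\.?", "",
                                                       fmtTrim(grid))))
  fmtTrim(v, max(digits, 2L))
}

#' Format a notation summary
#'
#' Renders \code{\{a/b/c\} (d) e-f (g) [h +/- i, j]} with the extreme
#' values in parentheses only when they lie outside [e, f]; e and f are
#' joined by an en-dash, or a single value is printed when e = f.
#'
#' @param s a \code{\link{NotationSummary}}.
#' @return character scalar.
#' @export
formatNotation <- function(s) {
  lo <- if (s@d < s@e - 1e-9) sprintf("(%s) ", .fmtBound(s@d, s@grid)) else ""
  hi <- if (s@g > s@f + 1e-9) sprintf(" (%s)", .fmtBound(s@g, s@grid)) else ""
  core <- if (abs(s@e - s@f) < 1e-9) .fmtBound(s@e, s@grid)
          else paste0(.fmtBound(s@e, s@grid), "\u2013", .fmtBound(s@f, s@grid))
  sprintf("{%d/%d/%d} %s%s%s [%.2f \u00b1 %.2f, %.2f]",
          s@a, s@b, s@c, lo, core, hi, s@h, s@i, s@j)
}

#' Parse a notation string
#'
#' Inverse of \code{\link{formatNotation}}; accepts en-dash or hyphen
#' between e and f and "+/-" or the plus-minus sign.
#'
#' @param text character scalar.
#' @param grid recording grid to attach to the result (default 0.5).
#' @return a \code{\link{NotationSummary}}.
#' @export
parseNotation <- function(text, grid = 0.5) {
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  pat <- paste0(
    "^\\{([0-9]+)/([0-9]+)/([0-9]+)\\} ",
    "(?:\\(", num, "\\) )?",
    num, "(?:(?:\u2013|-)", num, ")?",
    "(?: \\(", num, "\\))?",
    " \\[", num, " (?:\u00b1|\\+/-) ", num, ", ", num, "\\]$"
  )
  m <- regmatches(text, regexec(pat, text, perl = TRUE))[[1]]
  if (length(m) == 0) {
    # locate first divergence from the expected shape for the error message
    pos <- 1
    while (pos <= nchar(text) &&
           length(regmatches(substr(text, 1, pos),
                             regexec("^\\{[0-9/]*\\}?", substr(text, 1, pos))[[1]])))
      pos <- pos + 1
    validationError(sprintf("malformed notation string near position %d: %s",
                            pos, text))
  }
  val <- function(k) if (m[k + 1] == "") NA_real_ else as.numeric(m[k + 1])
  e <- val(4 + 1)
  f <- val(4 + 2); if (is.na(f)) f <- e
  d <- val(4); if (is.na(d)) d <- e
  g <- val(4 + 3); if (is.na(g)) g <- f
  new("NotationSummary",
      a = as.integer(m[2]), b = as.integer(m[3]), c = as.integer(m[4]),
      d = d, e = e, f = f, g = g,
      h = as.numeric(m[9]), i = as.numeric(m[10]), j = as.numeric(m[11]),
      grid = as.numeric(grid))
}

#' Shape-ratio summary (length/width)
#'
#' Computes the per-spore length/width ratio (the shape ratio printed as
#' \emph{Q} in taxonomic descriptions) before summarising; grid snapping is
#' disabled and everything is reported at 2 decimals.
#'
#' @param lengths,widths paired per-spore measurements.
#' @inheritParams summarizeMeasurements
#' @return a \code{\link{NotationSummary}} of the ratios.
#' @export
shapeRatio <- function(lengths, widths, nSporocarps = 1L, nCollections = 1L,
                       coverage = 0.9) {
  if (length(lengths) != length(widths))
    validationError("lengths and widths must be paired")
  if (any(widths <= 0))
    validationError("widths must be positive")
  summarizeMeasurements(lengths / widths, nSporocarps, nCollections,
                        coverage = coverage, grid = NA)
}

#' Summarise a spore measurement table
#'
#' @param df data.frame with columns \code{collection}, \code{sporocarp},
#'   \code{length_um}, \code{width_um}.
#' @inheritParams summarizeMeasurements
#' @return list with \code{length}, \code{width}, \code{ratio}
#'   (\code{NotationSummary} objects) and \code{text}, the rendered
#'   "length x width, Q = ratio" description.
#' @export
summarizeSpores <- function(df, coverage = 0.9, grid = 0.5) {
  miss <- setdiff(c("collection", "sporocarp", "length_um", "width_um"),
                  names(df))
  if (length(miss))
    validationError(sprintf("measurement table lacks column(s): %s",
                            paste(miss, collapse = ", ")))
  b <- length(unique(df$sporocarp))
  cc <- length(unique(df$collection))
  len <- summarizeMeasurements(df$length_um, b, cc, coverage, grid)
  wid <- summarizeMeasurements(df$width_um, b, cc, coverage, grid)
  rat <- shapeRatio(df$length_um, df$width_um, b, cc, coverage)
  list(length = len, width = wid, ratio = rat,
       text = sprintf("%s \u00d7 %s \u00b5m, Q = %s",
                      formatNotation(len),
                      sub("^\\{[0-9/]+\\} ", "", formatNotation(wid)),
                      sub("^\\{[0-9/]+\\} ", "", formatNotation(rat))))
}
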