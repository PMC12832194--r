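## NDVI response machinery: maximum-value compositing to monthly layers,
## drought-month-excluded baseline climatologies, absolute/percent
## anomalies, seasonal summaries and the growth-minimum lag.

#' Maximum value composite to monthly layers
#'
#' Assigns each 16-day composite to the month containing its start date and
#' takes the per-cell maximum over a month's composites, which suppresses
#' cloud-depressed values. Missing composites are ignored; a cell missing
#' in all of a month's composites is missing in the month.
#'
#' @param composites numeric array (rows x cols x ncomposite).
#' @param dates \code{Date} vector of composite start dates (one per layer).
#' @param varname,units,cellsize,origin metadata for the result.
#' @return a \code{\linkS4class{MonthlyStack}} covering the contiguous month
#'   range spanned by \code{dates}; months with zero assigned composites are
#'   all-\code{NA} layers and trigger a warning.
#' @examples
#' a <- array(c(0.31, 0.47), c(1, 1, 2))
#' mvcMonthly(a, as.Date(c("2010-01-01", "2010-01-17")))
#' @export
mvcMonthly <- function(composites, dates, varname = "NDVI",
                       units = "unitless", cellsize = 250,
                       origin = c(0, 0)) {
  stopifnot(length(dim(composites)) == 3L,
            dim(composites)[3] == length(dates))
  dates <- as.Date(dates)
  cym <- ymCode(as.integer(format(dates, "%Y")),
                as.integer(format(dates, "%m")))
  ym <- ymSeq(min(cym), max(cym))
  d <- dim(composites)
  out <- array(NA_real_, c(d[1], d[2], length(ym)))
  emptyMonths <- character()
  for (i in seq_along(ym)) {
    sel <- which(cym == ym[i])
    if (length(sel) == 0) {
      emptyMonths <- c(emptyMonths, ymLabel(ym[i]))
      next
    }
    mx <- composites[, , sel[1]]
    for (j in sel[-1]) mx <- pmax(mx, composites[, , j], na.rm = TRUE)
    out[, , i] <- mx
  }
  if (length(emptyMonths))
    warning("months with no assigned composites: ",
            paste(emptyMonths, collapse = ", "))
  monthlyStack(out, ym = ym, varname = varname, units = units,
               cellsize = cellsize, origin = origin)
}

#' Drought-excluded baseline climatology
#'
#' For each calendar month, the per-cell mean over years whose month is not
#' flagged as a drought month. Contributing-year counts are recorded; a
#' calendar month with every year excluded gets a missing baseline (or,
#' with \code{fallbackAllYears = TRUE}, the all-years mean).
#'
#' @param stack a \code{\linkS4class{MonthlyStack}}.
#' @param droughtMask logical vector along the stack's month index
#'   (\code{TRUE} = exclude from the baseline), e.g. from
#'   \code{\link{eventMask}}.
#' @param fallbackAllYears use the all-years mean where every year of a
#'   calendar month is excluded (default \code{FALSE}).
#' @return a \code{\linkS4class{Climatology}}.
#' @export
baselineClimatology <- function(stack, droughtMask = NULL,
                                fallbackAllYears = FALSE) {
  stopifnot(is(stack, "MonthlyStack"))
  ym <- monthIndex(stack)
  if (is.null(droughtMask)) droughtMask <- rep(FALSE, length(ym))
  stopifnot(length(droughtMask) == length(ym))
  mon <- ymMonth(ym)
  d <- dim(stack@values)
  base <- array(NA_real_, c(d[1], d[2], 12L))
  nContrib <- integer(12L)
  for (m in 1:12) {
    sel <- which(mon == m & !droughtMask)
    nContrib[m] <- length(sel)
    if (length(sel) == 0) {
      if (fallbackAllYears) {
        sel <- which(mon == m)
        if (length(sel) == 0) next
      } else next
    }
    sub <- matrix(stack@values[, , sel, drop = FALSE], d[1] * d[2],
                  length(sel))
    base[, , m] <- rowMeans(sub, na.rm = TRUE)
  }
  base[is.nan(base)] <- NA_real_
  new("Climatology", baseline = base, nContrib = nContrib,
      excluded = ym[droughtMask], varname = stack@varname,
      units = stack@units)
}

#' Absolute and percent anomalies
#'
#' \code{absolute = observed - baseline} (negative = below baseline);
#' \code{percent = 100 * absolute / baseline} where \code{|baseline| >=
#' epsilon}, otherwise flagged undefined (\code{NA}) while the absolute
#' anomaly is still reported.
#'
#' @param observed,baseline numeric scalars, vectors or arrays on a shared
#'   grid/scope.
#' @param epsilon smallest baseline magnitude for which percent anomalies
#'   are defined (default 0.01, appropriate for NDVI; pass a
#'   variable-specific value for hydrothermal fields).
#' @return list with elements \code{absolute} and \code{percent} (same
#'   shape as the inputs).
#' @examples
#' anomaly(0.45, 0.50)   # absolute -0.05, percent -10
#' @export
anomaly <- function(observed, baseline, epsilon = 0.01) {
  if (!identical(dim(observed), dim(baseline)) ||
      length(observed) != length(baseline))
    stop("observed and baseline must share grid and scope")
  absolute <- observed - baseline
  percent <- ifelse(abs(baseline) >= epsilon,
                    100 * absolute / baseline, NA_real_)
  list(absolute = absolute, percent = percent)
}

#' Monthly anomaly stack against a climatology
#'
#' Applies \code{\link{anomaly}} layer by layer, matching each month of the
#' stack to its calendar-month baseline.
#'
#' @param stack a \code{\linkS4class{MonthlyStack}}.
#' @param climatology a \code{\linkS4class{Climatology}} on the same grid.
#' @param epsilon passed to \code{\link{anomaly}}.
#' @return list of two \code{\linkS4class{MonthlyStack}}s:
#'   \code{absolute} and \code{percent}.
#' @export
anomalyStack <- function(stack, climatology, epsilon = 0.01) {
  stopifnot(is(stack, "MonthlyStack"), is(climatology, "Climatology"))
  ym <- monthIndex(stack)
  mon <- ymMonth(ym)
  d <- dim(stack@values)
  absv <- array(NA_real_, d)
  pctv <- array(NA_real_, d)
  for (i in seq_along(ym)) {
    a <- anomaly(stack@values[, , i],
                 climatology@baseline[, , mon[i]], epsilon)
    absv[, , i] <- a$absolute
    pctv[, , i] <- a$percent
  }
  list(
    absolute = monthlyStack(absv, ym = ym,
      varname = paste0(stack@varname, "_anom"), units = stack@units,
      cellsize = stack@cellsize, origin = stack@origin),
    percent = monthlyStack(pctv, ym = ym,
      varname = paste0(stack@varname, "_anom_pct"), units = "%",
      cellsize = stack@cellsize, origin = stack@origin))
}

#' Regional mean series
#'
#' Equal-weight mean over valid cells for each month (area weighting is
#' uniform on a regular grid).
#'
#' @param stack a \code{\linkS4class{MonthlyStack}}.
#' @return named numeric vector (names are \code{"YYYY-MM"} labels).
#' @export
regionalMeanSeries <- function(stack) {
  v <- apply(stack@values, 3, mean, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  stats::setNames(v, ymLabel(monthIndex(stack)))
}

#' Seasonal anomaly
#'
#' Mean of the member months' absolute anomalies; the percent anomaly is
#' computed against the seasonal baseline mean.
#'
#' @param monthlyAbsolute named numeric vector of monthly absolute
#'   anomalies indexed by ym code (names optional if \code{ym} given).
#' @param monthlyBaseline numeric vector of the matching monthly baseline
#'   values.
#' @param ym integer ym codes along both vectors.
#' @param season,year the season window (see \code{\link{seasonWindow}}).
#' @param epsilon percent-anomaly floor on the seasonal baseline.
#' @return list with \code{absolute} and \code{percent} scalars.
#' @export
seasonalAnomaly <- function(monthlyAbsolute, monthlyBaseline, ym,
                            season, year, epsilon = 0.01) {
  win <- seasonWindow(season, year)
  idx <- match(win, ym)
  if (any(is.na(idx)) || any(is.na(monthlyAbsolute[idx]))) {
    warning("seasonal anomaly undefined: member month(s) missing for ",
            season, " ", year)
    return(list(absolute = NA_real_, percent = NA_real_))
  }
  absSeason <- mean(monthlyAbsolute[idx])
  baseSeason <- mean(monthlyBaseline[idx])
  pct <- if (abs(baseSeason) >= epsilon) 100 * absSeason / baseSeason
         else NA_real_
  list(absolute = absSeason, percent = pct)
}

#' Shift of the annual growth minimum
#'
#' Signed difference, in months, between the observed and baseline annual
#' minima over the same 12 consecutive months: positive = observed minimum
#' delayed. Ties are broken toward the earliest month and flagged via the
#' \code{"ties"} attribute.
#'
#' @param observed,baseline numeric length-12 monthly curves.
#' @return integer lag in months, attribute \code{"ties"} TRUE if either
#'   curve's minimum was tied.
#' @examples
#' base <- c(10, 11, 12, 14, 16, 18, 20, 19, 17, 15, 13, 11)
#' obs <- c(12, 11, 10, 14, 16, 18, 20, 19, 17, 15, 13, 12)
#' minimumShift(obs, base)  # +2
#' @export
minimumShift <- function(observed, baseline) {
  stopifnot(length(observed) == 12L, length(baseline) == 12L)
  io <- which(observed == min(observed))
  ib <- which(baseline == min(baseline))
  ties <- length(io) > 1L || length(ib) > 1L
  lag <- as.integer(io[1] - ib[1])
  attr(lag, "ties") <- ties
  lag
}
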