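## Run-theory drought event extraction from an SPEI series: sub-threshold
## runs, short-gap pooling, minimum-duration filtering, and seasonal
## summaries.

#' Drought-month mask
#'
#' \code{TRUE} where SPEI <= threshold (the threshold itself counts as
#' drought). Months with undefined SPEI are \code{FALSE}; their positions
#' are attached as the \code{"undefined"} attribute.
#'
#' @param spei a \code{\linkS4class{SpeiSeries}} or numeric vector.
#' @param threshold drought threshold (default -1.0).
#' @return logical vector along the series.
#' @examples
#' droughtMonths(c(-0.9, -1.0, -1.1))
#' @export
droughtMonths <- function(spei, threshold = -1.0) {
  stopifnot(is.finite(threshold))
  v <- if (is(spei, "SpeiSeries")) speiValues(spei) else as.numeric(spei)
  mask <- !is.na(v) & v <= threshold
  attr(mask, "undefined") <- which(is.na(v))
  mask
}

# runs of TRUE in a logical vector -> matrix of (start, end) indices
.runsOf <- function(mask) {
  r <- rle(as.vector(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Identify drought events by run theory
#'
#' Maximal runs of sub-threshold months are pooled when separated by at
#' most \code{mergeGap} non-drought months (gap months count toward the
#' merged event's duration and mask), then events shorter than
#' \code{minDuration} months are discarded. Event severity is the class of
#' the peak (minimum) SPEI.
#'
#' @param spei a \code{\linkS4class{SpeiSeries}}.
#' @param threshold drought threshold (default -1.0).
#' @param minDuration minimum event duration in months after merging
#'   (default 2: events must last longer than one month).
#' @param mergeGap maximum non-drought gap, in months, that is absorbed
#'   into a single event (default 1).
#' @return data.frame with one row per event: \code{event_id},
#'   \code{onset}/\code{termination} (ym codes), \code{onset_label},
#'   \code{termination_label}, \code{duration_months}, \code{peak_spei},
#'   \code{event_class}, and a list column \code{month_classes} of
#'   per-month severity factors.
#' @examples
#' cl <- simulateClimate(scenarioConfig(seed = 1))$stations[[1]]
#' identifyEvents(computeSpei(cl))
#' @export
identifyEvents <- function(spei, threshold = -1.0, minDuration = 2L,
                           mergeGap = 1L) {
  stopifnot(is(spei, "SpeiSeries"), mergeGap >= 0L)
  v <- speiValues(spei)
  ym <- monthIndex(spei)
  empty <- data.frame(event_id = integer(), onset = integer(),
                      termination = integer(),
                      onset_label = character(),
                      termination_label = character(),
                      duration_months = integer(), peak_spei = numeric(),
                      event_class = character(),
                      stringsAsFactors = FALSE)
  empty$month_classes <- list()
  if (length(v) == 0) return(empty)
  mask <- droughtMonths(v, threshold)
  runs <- .runsOf(mask)
  if (nrow(runs) == 0) return(empty)
  # pool runs separated by <= mergeGap non-drought months
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap <- runs[i, "start"] - merged[nrow(merged), "end"] - 1L
    if (gap <= mergeGap) {
      merged[nrow(merged), "end"] <- runs[i, "end"]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  dur <- merged[, "end"] - merged[, "start"] + 1L
  keep <- dur >= minDuration
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  peak <- vapply(seq_len(nrow(merged)), function(i)
    min(v[merged[i, "start"]:merged[i, "end"]], na.rm = TRUE), numeric(1))
  out <- data.frame(
    event_id = seq_len(nrow(merged)),
    onset = ym[merged[, "start"]],
    termination = ym[merged[, "end"]],
    onset_label = ymLabel(ym[merged[, "start"]]),
    termination_label = ymLabel(ym[merged[, "end"]]),
    duration_months = merged[, "end"] - merged[, "start"] + 1L,
    peak_spei = peak,
    event_class = as.character(classifySeverity(peak)),
    stringsAsFactors = FALSE)
  out$month_classes <- lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged[i, "start"]:merged[i, "end"]
    stats::setNames(classifySeverity(ifelse(is.na(v[idx]), 0, v[idx])),
                    ymLabel(ym[idx]))
  })
  out
}

#' Month mask covered by drought events
#'
#' \code{TRUE} exactly on months inside any identified event, including
#' merged gap months. This is the exclusion mask used when building
#' drought-free baselines.
#'
#' @param events an event table from \code{\link{identifyEvents}}.
#' @param ym integer ym codes of the series the mask should cover.
#' @return logical vector along \code{ym}.
#' @export
eventMask <- function(events, ym) {
  mask <- rep(FALSE, length(ym))
  for (i in seq_len(nrow(events)))
    mask[ym >= events$onset[i] & ym <= events$termination[i]] <- TRUE
  mask
}

#' Meteorological season window
#'
#' Spring = Mar-May, summer = Jun-Aug, autumn = Sep-Nov; winter of year Y
#' spans Dec Y, Jan Y+1 and Feb Y+1.
#'
#' @param season one of \code{"spring"}, \code{"summer"}, \code{"autumn"},
#'   \code{"winter"}.
#' @param year season year label.
#' @return integer ym codes of the three member months.
#' @examples
#' ymLabel(seasonWindow("winter", 2009))  # Dec 2009 .. Feb 2010
#' @export
seasonWindow <- function(season, year) {
  season <- match.arg(season, c("spring", "summer", "autumn", "winter"))
  switch(season,
    spring = ymCode(rep(year, 3), 3:5),
    summer = ymCode(rep(year, 3), 6:8),
    autumn = ymCode(rep(year, 3), 9:11),
    winter = c(ymCode(year, 12), ymCode(year + 1, 1:2)))
}

#' Seasonal mean SPEI
#'
#' Arithmetic mean of the season's three member months; missing members
#' yield \code{NA} with a warning.
#'
#' @param spei a \code{\linkS4class{SpeiSeries}}.
#' @param season,year passed to \code{\link{seasonWindow}}.
#' @return a single numeric value.
#' @export
seasonalMeanSpei <- function(spei, season, year) {
  win <- seasonWindow(season, year)
  v <- speiValues(spei)[match(win, monthIndex(spei))]
  if (any(is.na(v))) {
    warning("seasonal mean undefined: member month(s) missing for ",
            season, " ", year)
    return(NA_real_)
  }
  mean(v)
}
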