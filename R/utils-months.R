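#' Month-index utilities
#'
#' The package indexes monthly series by a single integer, the "year-month"
#' code \code{ym = 12 * year + (month - 1)}. Consecutive calendar months map
#' to consecutive integers, so contiguity, rolling windows and set operations
#' reduce to integer arithmetic.
#'
#' @param year,month integer vectors of calendar years and months (1-12).
#' @param ym integer year-month codes.
#' @return \code{ymCode} returns integer codes; \code{ymYear} and
#'   \code{ymMonth} invert them; \code{ymLabel} formats codes as
#'   \code{"YYYY-MM"}.
#' @examples
#' ymCode(2009, 10) + 0:7   # Oct 2009 .. May 2010
#' ymMonth(ymCode(2009, 12) + 1) # wraps to January
#' @export
ymCode <- function(year, month) {
  stopifnot(all(month %in% 1:12))
  as.integer(12L * as.integer(year) + (as.integer(month) - 1L))
}

#' @rdname ymCode
#' @export
ymYear <- function(ym) as.integer(ym %/% 12L)

#' @rdname ymCode
#' @export
ymMonth <- function(ym) as.integer(ym %% 12L) + 1L

#' @rdname ymCode
#' @export
ymLabel <- function(ym) sprintf("%04d-%02d", ymYear(ym), ymMonth(ym))

#' Contiguous month sequence
#' @param from,to integer ym codes (inclusive).
#' @return integer vector of consecutive ym codes.
#' @export
ymSeq <- function(from, to) seq.int(as.integer(from), as.integer(to))

# internal: check a ym vector is contiguous and ascending
isContiguous <- function(ym) {
  length(ym) <= 1L || all(diff(as.integer(ym)) == 1L)
}
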