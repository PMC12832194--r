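#' @import methods
NULL

#' ClimateSeries: monthly station climate
#'
#' Holds one station's contiguous monthly record of mean temperature and
#' precipitation total, with explicit \code{NA} for missing months (never
#' silent zeros).
#'
#' @slot stationId character scalar station identifier.
#' @slot latitude,longitude decimal degrees.
#' @slot elevation metres above sea level.
#' @slot ym integer year-month codes (see \code{\link{ymCode}}), contiguous.
#' @slot tmp numeric mean temperature, degrees C (\code{NA} = missing).
#' @slot pre numeric precipitation total, mm/month, non-negative where
#'   observed (\code{NA} = missing).
#' @export
setClass("ClimateSeries",
  representation(
    stationId = "character",
    latitude  = "numeric",
    longitude = "numeric",
    elevation = "numeric",
    ym        = "integer",
    tmp       = "numeric",
    pre       = "numeric"
  )
)

setValidity("ClimateSeries", function(object) {
  msg <- character()
  n <- length(object@ym)
  if (length(object@tmp) != n || length(object@pre) != n)
    msg <- c(msg, "tmp, pre and ym must have equal length")
  if (!isContiguous(object@ym))
    msg <- c(msg, "month index must be contiguous and ascending")
  if (any(object@pre < 0, na.rm = TRUE))
    msg <- c(msg, "precipitation must be non-negative where observed")
  if (length(object@latitude) != 1L || abs(object@latitude) > 90)
    msg <- c(msg, "latitude must be a single value in [-90, 90]")
  if (length(msg)) msg else TRUE
})

#' Construct a ClimateSeries
#'
#' @param stationId station identifier.
#' @param latitude,longitude decimal degrees.
#' @param elevation metres.
#' @param year,month calendar labels for each row.
#' @param tmp mean temperature (degrees C), \code{NA} where missing.
#' @param pre precipitation total (mm/month), \code{NA} where missing.
#' @return a \code{\linkS4class{ClimateSeries}}.
#' @examples
#' cs <- climateSeries("S1", 26.5, 106.7, 1100,
#'   year = rep(2001, 12), month = 1:12,
#'   tmp = c(5, 6, 10, 15, 19, 22, 24, 23, 20, 15, 10, 6),
#'   pre = c(20, 25, 40, 90, 140, 180, 195, 165, 105, 65, 40, 35))
#' cs
#' @export
climateSeries <- function(stationId, latitude, longitude, elevation,
                          year, month, tmp, pre) {
  new("ClimateSeries",
      stationId = as.character(stationId),
      latitude = as.numeric(latitude), longitude = as.numeric(longitude),
      elevation = as.numeric(elevation),
      ym = ymCode(year, month),
      tmp = as.numeric(tmp), pre = as.numeric(pre))
}

#' SpeiSeries: standardized k-month water-balance index
#'
#' Monthly SPEI values together with the per-calendar-month log-logistic
#' parameters that produced them and the calibration period used for fitting.
#'
#' @slot ym integer year-month codes, contiguous.
#' @slot spei numeric standardized values (\code{NA} where the k-month
#'   aggregate is undefined).
#' @slot k integer aggregation timescale in months.
#' @slot params list of 12 fitted parameter sets (one per calendar month),
#'   each \code{list(alpha, beta, gamma, n, lmom)}.
#' @slot calibration integer length-2 ym range used for fitting.
#' @export
setClass("SpeiSeries",
  representation(
    ym = "integer", spei = "numeric", k = "integer",
    params = "list", calibration = "integer"
  )
)

setValidity("SpeiSeries", function(object) {
  msg <- character()
  if (length(object@spei) != length(object@ym))
    msg <- c(msg, "spei and ym must have equal length")
  if (!isContiguous(object@ym))
    msg <- c(msg, "month index must be contiguous")
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (any(is.infinite(object@spei)))
    msg <- c(msg, "spei must be finite wherever defined")
  if (length(msg)) msg else TRUE
})

#' MonthlyStack: gridded monthly time series
#'
#' A (rows x cols x months) array of one variable (NDVI or a hydrothermal
#' field) on a regular grid, with calendar month indexing shared across
#' layers.
#'
#' @slot values numeric array, dim \code{c(nrow, ncol, nmonth)}.
#' @slot ym integer year-month codes, one per layer, contiguous.
#' @slot varname variable name (e.g. \code{"NDVI"}, \code{"PRE"}).
#' @slot units unit string (e.g. \code{"unitless"}, \code{"mm"}).
#' @slot cellsize cell edge length (metres).
#' @slot origin numeric length-2 (x, y) of the lower-left corner.
#' @export
setClass("MonthlyStack",
  representation(
    values = "array", ym = "integer", varname = "character",
    units = "character", cellsize = "numeric", origin = "numeric"
  )
)

setValidity("MonthlyStack", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-d array (rows x cols x months)")
  else if (d[3] != length(object@ym))
    msg <- c(msg, "third dimension must match the month index length")
  if (!isContiguous(object@ym))
    msg <- c(msg, "month index must be contiguous")
  if (identical(object@varname, "NDVI") &&
      any(abs(object@values) > 1, na.rm = TRUE))
    msg <- c(msg, "NDVI values must lie in [-1, 1] (flag invalid cells NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a MonthlyStack
#' @param values rows x cols x months array.
#' @param year,month calendar labels per layer (or \code{ym} directly).
#' @param ym optional precomputed year-month codes.
#' @param varname,units variable name and units.
#' @param cellsize,origin grid geometry (metres; lower-left corner).
#' @return a \code{\linkS4class{MonthlyStack}}.
#' @export
monthlyStack <- function(values, year = NULL, month = NULL, ym = NULL,
                         varname = "NDVI", units = "unitless",
                         cellsize = 250, origin = c(0, 0)) {
  if (is.null(ym)) ym <- ymCode(year, month)
  new("MonthlyStack", values = values, ym = as.integer(ym),
      varname = varname, units = units,
      cellsize = as.numeric(cellsize), origin = as.numeric(origin))
}

#' Climatology: drought-excluded monthly baselines
#'
#' Twelve per-calendar-month baseline layers (means over contributing,
#' i.e. non-drought, years) plus per-month contributing-year counts.
#'
#' @slot baseline numeric array, dim \code{c(nrow, ncol, 12)}.
#' @slot nContrib integer length-12 count of contributing years per
#'   calendar month.
#' @slot excluded integer ym codes that were excluded as drought months.
#' @slot varname,units provenance of the summarized variable.
#' @export
setClass("Climatology",
  representation(
    baseline = "array", nContrib = "integer",
    excluded = "integer", varname = "character", units = "character"
  )
)

setValidity("Climatology", function(object) {
  d <- dim(object@baseline)
  msg <- character()
  if (length(d) != 3L || d[3] != 12L)
    msg <- c(msg, "baseline must be rows x cols x 12")
  if (length(object@nContrib) != 12L)
    msg <- c(msg, "nContrib must have length 12")
  if (length(msg)) msg else TRUE
})

#' CategoricalMask: grid-aligned class raster
#'
#' Integer class codes on the analysis grid with a label map; \code{NA}
#' marks invalid cells.
#'
#' @slot values integer matrix of class codes.
#' @slot labels named character vector mapping code (as name) to label.
#' @export
setClass("CategoricalMask",
  representation(values = "matrix", labels = "character")
)

setValidity("CategoricalMask", function(object) {
  msg <- character()
  present <- sort(unique(as.vector(object@values)))
  present <- present[!is.na(present)]
  if (!all(as.character(present) %in% names(object@labels)))
    msg <- c(msg, "label map must cover all class codes present")
  if (length(msg)) msg else TRUE
})

#' Construct a CategoricalMask
#' @param values integer matrix of class codes (\code{NA} = invalid cell).
#' @param labels named character, names are the codes as strings.
#' @return a \code{\linkS4class{CategoricalMask}}.
#' @export
categoricalMask <- function(values, labels) {
  storage.mode(values) <- "integer"
  new("CategoricalMask", values = values, labels = labels)
}

#' VariogramModel: exponential semivariogram
#'
#' \eqn{\gamma(h) = nugget + psill (1 - e^{-h/range})}; the total sill is
#' \code{nugget + psill} and the practical range about \code{3 * range}.
#'
#' @slot nugget,psill,range model parameters (nugget, partial sill >= 0;
#'   range > 0).
#' @slot empirical data.frame of binned empirical semivariances
#'   (\code{dist}, \code{gamma}, \code{np}).
#' @export
setClass("VariogramModel",
  representation(nugget = "numeric", psill = "numeric", range = "numeric",
                 empirical = "data.frame")
)

setValidity("VariogramModel", function(object) {
  msg <- character()
  if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
  if (object@psill < 0) msg <- c(msg, "partial sill must be >= 0")
  if (object@range <= 0) msg <- c(msg, "range must be > 0")
  if (length(msg)) msg else TRUE
})
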