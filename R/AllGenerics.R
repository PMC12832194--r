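#' Accessors for month-indexed objects
#'
#' @param x a \code{ClimateSeries}, \code{SpeiSeries} or
#'   \code{MonthlyStack}.
#' @return \code{monthIndex} returns the integer ym codes;
#'   \code{speiValues}, \code{temperature} and \code{precipitation} the
#'   respective numeric series; \code{stackValues} the 3-d array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("monthIndex", function(x) standardGeneric("monthIndex"))

#' @rdname accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' @rdname accessors
#' @export
setGeneric("precipitation", function(x) standardGeneric("precipitation"))

#' @rdname accessors
#' @export
setGeneric("speiValues", function(x) standardGeneric("speiValues"))

#' @rdname accessors
#' @export
setGeneric("stackValues", function(x) standardGeneric("stackValues"))

#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

setMethod("monthIndex", "ClimateSeries", function(x) x@ym)
setMethod("monthIndex", "SpeiSeries", function(x) x@ym)
setMethod("monthIndex", "MonthlyStack", function(x) x@ym)
setMethod("temperature", "ClimateSeries", function(x) x@tmp)
setMethod("precipitation", "ClimateSeries", function(x) x@pre)
setMethod("speiValues", "SpeiSeries", function(x) x@spei)
setMethod("stackValues", "MonthlyStack", function(x) x@values)
setMethod("maskValues", "CategoricalMask", function(x) x@values)
setMethod("maskLabels", "CategoricalMask", function(x) x@labels)

setMethod("show", "ClimateSeries", function(object) {
  n <- length(object@ym)
  cat("ClimateSeries", object@stationId,
      sprintf("(%.3f N, %.3f E, %.0f m)\n",
              object@latitude, object@longitude, object@elevation))
  cat(sprintf("  %d months: %s .. %s | missing tmp %d, pre %d\n",
              n, ymLabel(object@ym[1]), ymLabel(object@ym[n]),
              sum(is.na(object@tmp)), sum(is.na(object@pre))))
})

setMethod("show", "SpeiSeries", function(object) {
  n <- length(object@ym)
  def <- !is.na(object@spei)
  cat(sprintf("SpeiSeries (k = %d): %d months, %d defined\n",
              object@k, n, sum(def)))
  if (any(def))
    cat(sprintf("  range [%.2f, %.2f] | calibration %s .. %s\n",
                min(object@spei[def]), max(object@spei[def]),
                ymLabel(object@calibration[1]),
                ymLabel(object@calibration[2])))
})

setMethod("show", "MonthlyStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("MonthlyStack %s [%s]: %d x %d grid, %d months (%s .. %s)\n",
              object@varname, object@units, d[1], d[2], d[3],
              ymLabel(object@ym[1]), ymLabel(object@ym[length(object@ym)])))
})

setMethod("show", "CategoricalMask", function(object) {
  v <- as.vector(object@values)
  tab <- table(factor(object@labels[as.character(v)],
                      levels = unname(object@labels)))
  share <- round(100 * tab / sum(tab), 1)
  cat("CategoricalMask:", paste(names(tab), paste0(share, "%"),
                                collapse = ", "), "\n")
})

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "VariogramModel (exponential): nugget %.4g, psill %.4g, range %.4g\n",
    object@nugget, object@psill, object@range))
})

setMethod("show", "Climatology", function(object) {
  d <- dim(object@baseline)
  cat(sprintf(
    "Climatology %s [%s]: %d x %d grid, contributing years %d..%d, %d excluded months\n",
    object@varname, object@units, d[1], d[2],
    min(object@nContrib), max(object@nContrib), length(object@excluded)))
})
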