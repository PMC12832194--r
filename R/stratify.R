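## Zonal summaries of gridded fields by categorical strata (vegetation
## type, karst/non-karst landform) and their cross-classification.

#' Zonal summary of a field by categorical mask
#'
#' Per-class n, mean, sd, min and max over cells valid in both the field
#' and the mask (listwise dropping). Classes named in
#' \code{excludeLabels} (default \code{"OTH"}: croplands, urban, barren,
#' wetlands) are dropped from vegetation-response summaries.
#'
#' @param field numeric matrix on the analysis grid.
#' @param mask a \code{\linkS4class{CategoricalMask}} on the same grid.
#' @param includeLabels optional character vector of labels to report; a
#'   requested label absent from the mask is omitted with a warning.
#' @param excludeLabels labels dropped when \code{includeLabels} is
#'   \code{NULL}.
#' @param scope optional time-scope tag copied into the result.
#' @return data.frame: \code{stratum}, \code{n}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}, \code{scope}.
#' @examples
#' f <- matrix(1:4, 2)
#' m <- categoricalMask(matrix(c(1L, 1L, 2L, 2L), 2),
#'                      c("1" = "A", "2" = "B"))
#' zonalSummary(f, m)
#' @export
zonalSummary <- function(field, mask, includeLabels = NULL,
                         excludeLabels = "OTH", scope = NA_character_) {
  stopifnot(is(mask, "CategoricalMask"),
            identical(dim(field), dim(maskValues(mask))))
  labs <- maskLabels(mask)
  cls <- labs[as.character(as.vector(maskValues(mask)))]
  val <- as.vector(field)
  ok <- !is.na(val) & !is.na(cls)
  if (is.null(includeLabels)) {
    includeLabels <- setdiff(unname(labs), excludeLabels)
  } else {
    missingLabs <- setdiff(includeLabels, cls[ok])
    if (length(missingLabs))
      warning("class(es) absent from mask: ",
              paste(missingLabs, collapse = ", "))
  }
  keep <- ok & cls %in% includeLabels
  if (!any(keep))
    return(data.frame(stratum = character(), n = integer(),
                      mean = numeric(), sd = numeric(), min = numeric(),
                      max = numeric(), scope = character(),
                      stringsAsFactors = FALSE))
  g <- factor(cls[keep], levels = intersect(includeLabels, unique(cls[keep])))
  v <- val[keep]
  out <- data.frame(
    stratum = levels(g),
    n = as.integer(tapply(v, g, length)),
    mean = as.numeric(tapply(v, g, mean)),
    sd = as.numeric(tapply(v, g, stats::sd)),
    min = as.numeric(tapply(v, g, min)),
    max = as.numeric(tapply(v, g, max)),
    scope = scope, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-classified zonal summary
#'
#' One summary row per (vegetation class, landform class) pair with at
#' least one valid cell; empty intersections are absent from the table.
#'
#' @param field numeric matrix.
#' @param vegMask,landformMask aligned \code{CategoricalMask}s.
#' @param excludeVeg vegetation labels to drop (default \code{"OTH"}).
#' @param scope optional time-scope tag.
#' @return data.frame: \code{veg}, \code{landform}, \code{n}, \code{mean},
#'   \code{sd}, \code{min}, \code{max}, \code{scope}.
#' @export
crossStratify <- function(field, vegMask, landformMask,
                          excludeVeg = "OTH", scope = NA_character_) {
  stopifnot(identical(dim(field), dim(maskValues(vegMask))),
            identical(dim(field), dim(maskValues(landformMask))))
  veg <- maskLabels(vegMask)[as.character(as.vector(maskValues(vegMask)))]
  lf <- maskLabels(landformMask)[
    as.character(as.vector(maskValues(landformMask)))]
  val <- as.vector(field)
  keep <- !is.na(val) & !is.na(veg) & !is.na(lf) & !(veg %in% excludeVeg)
  if (!any(keep))
    return(data.frame(veg = character(), landform = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      min = numeric(), max = numeric(), scope = character(),
                      stringsAsFactors = FALSE))
  key <- interaction(veg[keep], lf[keep], drop = TRUE, sep = "|")
  v <- val[keep]
  parts <- strsplit(levels(key), "|", fixed = TRUE)
  out <- data.frame(
    veg = vapply(parts, `[`, "", 1),
    landform = vapply(parts, `[`, "", 2),
    n = as.integer(tapply(v, key, length)),
    mean = as.numeric(tapply(v, key, mean)),
    sd = as.numeric(tapply(v, key, stats::sd)),
    min = as.numeric(tapply(v, key, min)),
    max = as.numeric(tapply(v, key, max)),
    scope = scope, stringsAsFactors = FALSE)
  out <- out[order(out$veg, out$landform), ]
  rownames(out) <- NULL
  out
}

# per-variable percent-anomaly floors (units of the variable)
.EPSILON_REGISTRY <- c(NDVI = 0.01, TMP = 0.5, PRE = 1, SR = 1,
                       RM = 0.01, SM = 0.01)

#' Hydrothermal anomaly series, optionally stratified
#'
#' Applies the drought-excluded baseline / anomaly machinery to a
#' hydrothermal variable stack and summarizes each month's anomaly field,
#' whole-domain or per stratum.
#'
#' @param stack a \code{\linkS4class{MonthlyStack}} whose \code{varname}
#'   is registered (NDVI, TMP, PRE, SR, RM, SM).
#' @param droughtMask logical exclusion mask along the stack months.
#' @param mask optional \code{\linkS4class{CategoricalMask}} for
#'   stratification; \code{NULL} summarizes the whole domain.
#' @param includeLabels,excludeLabels passed to \code{\link{zonalSummary}}.
#' @return data.frame: \code{ym}, \code{month_label}, \code{stratum},
#'   \code{n}, \code{absolute}, \code{percent}.
#' @export
hydrothermalSummary <- function(stack, droughtMask, mask = NULL,
                                includeLabels = NULL,
                                excludeLabels = "OTH") {
  stopifnot(is(stack, "MonthlyStack"))
  if (!stack@varname %in% names(.EPSILON_REGISTRY))
    stop("unregistered variable '", stack@varname,
         "'; expected one of ", paste(names(.EPSILON_REGISTRY),
                                      collapse = ", "))
  eps <- .EPSILON_REGISTRY[[stack@varname]]
  clim <- baselineClimatology(stack, droughtMask)
  an <- anomalyStack(stack, clim, epsilon = eps)
  ym <- monthIndex(stack)
  rows <- list()
  for (i in seq_along(ym)) {
    absF <- an$absolute@values[, , i]
    pctF <- an$percent@values[, , i]
    if (is.null(mask)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ym = ym[i], month_label = ymLabel(ym[i]), stratum = "ALL",
        n = sum(!is.na(absF)),
        absolute = mean(absF, na.rm = TRUE),
        percent = mean(pctF, na.rm = TRUE), stringsAsFactors = FALSE)
    } else {
      za <- zonalSummary(absF, mask, includeLabels, excludeLabels)
      zp <- zonalSummary(pctF, mask, includeLabels, excludeLabels)
      if (nrow(za))
        rows[[length(rows) + 1L]] <- data.frame(
          ym = ym[i], month_label = ymLabel(ym[i]), stratum = za$stratum,
          n = za$n, absolute = za$mean,
          percent = zp$mean[match(za$stratum, zp$stratum)],
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$absolute[is.nan(out$absolute)] <- NA_real_
  out$percent[is.nan(out$percent)] <- NA_real_
  rownames(out) <- NULL
  out
}
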