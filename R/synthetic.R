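## Seeded synthetic inputs emulating the study's four data families:
## monsoon station climate with planted drought episodes, 16-day NDVI
## composite stacks with class-specific lagged drought sensitivity,
## gridded hydrothermal variables, and categorical vegetation / landform
## masks. Every generator is deterministic given the scenario seed.

#' Default synthetic scenario configuration
#'
#' Encodes the study conditions the generators emulate: a subtropical
#' monsoon climate (mean ~15 C, January ~5.5 C, July ~24.5 C; ~1100 mm/yr
#' with ~80 percent falling April-October), one planted 8-month drought
#' episode (May through December of the drought year: a halving of
#' precipitation with slight warming, followed by a multi-month wet
#' rebound as the monsoon returns), vegetation classes with drought
#' sensitivities ordered MDW > SCR > BDF > GRA > NDF and a 2-month NDVI
#' response lag, and a 1.5x karst amplification of drought sensitivity.
#'
#' @param seed mandatory integer seed; all generator randomness derives
#'   from it.
#' @param years,startYear record length and first calendar year.
#' @param nrow,ncol,cellsize analysis grid (250 m cells by default).
#' @param nStations number of synthetic climate stations.
#' @param tmpMean,tmpAmp,tmpNoiseSd temperature sinusoid (degrees C) and
#'   station noise.
#' @param preMeans length-12 monthly precipitation means (mm), January
#'   first.
#' @param preCV per-month precipitation coefficient of variation (gamma
#'   marginal).
#' @param regionalSd lognormal sd of the shared regional monthly
#'   precipitation factor (induces inter-station correlation).
#' @param droughts list of planted episodes, each
#'   \code{list(startYear, startMonth, months, preMultiplier, tmpOffset)}.
#' @param reboundMonths,reboundMultiplier wet rebound applied right after
#'   each planted episode.
#' @param vegShares named target class shares (fractions of cells).
#' @param karstShare karst fraction of cells.
#' @param ndviMean,ndviAmp named per-class seasonal NDVI curve parameters
#'   (annual mean and half-amplitude; minimum in January, peak in July).
#' @param sensitivity named per-class NDVI response (NDVI units per unit
#'   of negative SPEI).
#' @param responseLag NDVI response lag in months.
#' @param karstAmplification multiplier on sensitivity over karst cells.
#' @param ndviNoiseSd,cloudSd per-composite measurement noise and
#'   one-sided cloud suppression scale.
#' @param threshold,k drought threshold and SPEI timescale used when
#'   deriving the expected drought window.
#' @return a list of class \code{"ScenarioConfig"}.
#' @export
scenarioConfig <- function(seed,
    years = 21L, startYear = 2001L,
    nrow = 60L, ncol = 60L, cellsize = 250,
    nStations = 12L,
    tmpMean = 15, tmpAmp = 9.5, tmpNoiseSd = 0.8,
    preMeans = c(30, 35, 50, 90, 140, 180, 195, 165, 105, 65, 40, 35),
    preCV = 0.3, regionalSd = 0.25,
    droughts = list(list(startYear = 2011L, startMonth = 5L,
                         months = 8L, preMultiplier = 0.5,
                         tmpOffset = 1.0)),
    reboundMonths = 3L, reboundMultiplier = 1.8,
    vegShares = c(BDF = 0.0332, NDF = 0.1250, SCR = 0.3148,
                  MDW = 0.0180, GRA = 0.1562, OTH = 0.3528),
    karstShare = 0.73,
    ndviMean = c(BDF = 0.72, NDF = 0.70, SCR = 0.62, MDW = 0.52,
                 GRA = 0.58, OTH = 0.45),
    ndviAmp = c(BDF = 0.12, NDF = 0.10, SCR = 0.18, MDW = 0.26,
                GRA = 0.22, OTH = 0.15),
    sensitivity = c(MDW = 0.070, SCR = 0.050, BDF = 0.040,
                    GRA = 0.033, NDF = 0.018, OTH = 0.030),
    responseLag = 2L, karstAmplification = 1.5,
    ndviNoiseSd = 0.015, cloudSd = 0.04,
    threshold = -1.0, k = 6L) {
  if (missing(seed)) stop("a seed is mandatory")
  for (d in droughts)
    if (d$preMultiplier <= 0 || d$preMultiplier > 1)
      stop("drought precipitation multiplier must be in (0, 1]")
  stopifnot(length(preMeans) == 12L, all(is.finite(sensitivity)))
  cfg <- as.list(environment())
  class(cfg) <- "ScenarioConfig"
  cfg
}

# ym codes of a planted forcing window
.forcingWindow <- function(d) {
  ymCode(d$startYear, d$startMonth) + seq_len(d$months) - 1L
}

# per-month precipitation multiplier series over the record (forcing +
# rebound), and PET offset series from the drought temperature offsets
.forcingSeries <- function(config) {
  ym <- ymSeq(ymCode(config$startYear, 1L),
              ymCode(config$startYear + config$years - 1L, 12L))
  mult <- rep(1, length(ym))
  toff <- rep(0, length(ym))
  for (d in config$droughts) {
    win <- .forcingWindow(d)
    mult[ym %in% win] <- d$preMultiplier
    toff[ym %in% win] <- d$tmpOffset
    reb <- max(win) + seq_len(config$reboundMonths)
    mult[ym %in% reb] <- config$reboundMultiplier
  }
  list(ym = ym, mult = mult, tmpOffset = toff)
}

#' Expected drought window implied by the planted forcing
#'
#' The 6-month index integrates the forcing, so the window over which the
#' index is expected at or below the threshold is not the forcing window
#' itself. This derives it analytically from the configuration alone: the
#' expected k-month deficit is the sum of forced mean-precipitation
#' deficits over the window, its scale the regional series' climatological
#' k-month standard deviation (station-averaged gamma noise plus the shared
#' regional factor), with small corrections for the forced months'
#' contamination of the calibration mean and spread. Independent of any
#' realized simulation.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return integer ym codes of the expected drought window(s).
#' @export
expectedDroughtWindow <- function(config) {
  f <- .forcingSeries(config)
  mon <- ymMonth(f$ym)
  meanP <- config$preMeans[mon]
  # expected deficit (positive = drier) per month incl. the wet rebound
  defic <- (1 - f$mult) * meanP
  # regional monthly sd: station gamma noise averages over stations, the
  # lognormal regional factor is shared
  sdFactor <- sqrt(config$preCV^2 / config$nStations + config$regionalSd^2)
  sdP <- sdFactor * meanP
  k <- config$k
  n <- length(f$ym)
  z <- rep(NA_real_, n)
  for (m in k:n) {
    w <- (m - k + 1L):m
    Delta <- sum(defic[w])
    S <- sqrt(sum(sdP[w]^2))
    if (S <= 0) next
    zf <- Delta / S
    shrink <- 1 - 1 / config$years        # forced month shifts the calib mean
    infl <- sqrt(1 + zf^2 / config$years) # and inflates the calib spread
    z[m] <- -(Delta * shrink) / (S * infl)
  }
  f$ym[!is.na(z) & z <= config$threshold]
}

#' Simulate station climate with planted droughts
#'
#' Temperature is a seasonal sinusoid (peak July) plus station noise and
#' the planted warming offsets; precipitation is gamma-distributed per
#' calendar month (shape \code{1/CV^2}), scaled by a shared lognormal
#' regional monthly factor and by the planted deficit/rebound multipliers.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return list: \code{stations} (list of
#'   \code{\linkS4class{ClimateSeries}}), \code{xy} (data.frame of station
#'   grid coordinates), \code{groundTruth} (forcing windows, expected
#'   drought window, sensitivity ordering, karst contrast).
#' @examples
#' sim <- simulateClimate(scenarioConfig(seed = 7))
#' sim$stations[[1]]
#' @export
simulateClimate <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  if (config$years < 15L)
    warning("fewer than 15 years: SPEI calibration will be unstable")
  set.seed(config$seed + 101L)
  f <- .forcingSeries(config)
  n <- length(f$ym)
  mon <- ymMonth(f$ym)
  regional <- exp(stats::rnorm(n, -config$regionalSd^2 / 2,
                               config$regionalSd))
  shape <- 1 / config$preCV^2
  ext <- c(config$ncol * config$cellsize, config$nrow * config$cellsize)
  stations <- vector("list", config$nStations)
  xy <- data.frame(station_id = character(config$nStations),
                   x = numeric(config$nStations),
                   y = numeric(config$nStations))
  for (s in seq_len(config$nStations)) {
    lat <- stats::runif(1, 24.6, 29.2)
    tmp <- config$tmpMean + config$tmpAmp * cos(2 * pi * (mon - 7) / 12) +
      f$tmpOffset + stats::rnorm(n, 0, config$tmpNoiseSd)
    meanP <- config$preMeans[mon]
    pre <- stats::rgamma(n, shape = shape, scale = meanP / shape) *
      regional * f$mult
    id <- sprintf("S%02d", s)
    stations[[s]] <- climateSeries(id, lat, 103.6 + s * 0.4,
                                   stats::runif(1, 400, 2000),
                                   ymYear(f$ym), mon, tmp, pre)
    xy$station_id[s] <- id
    xy$x[s] <- stats::runif(1, 0.02, 0.98) * ext[1]
    xy$y[s] <- stats::runif(1, 0.02, 0.98) * ext[2]
  }
  gt <- list(
    forcingWindows = lapply(config$droughts, .forcingWindow),
    expectedWindow = expectedDroughtWindow(config),
    sensitivityOrder = names(sort(config$sensitivity[
      setdiff(names(config$sensitivity), "OTH")], decreasing = TRUE)),
    karstAmplification = config$karstAmplification)
  list(stations = stations, xy = xy, groundTruth = gt)
}

#' Pool stations into a regional climate series
#'
#' Equal-weight mean of station temperature and precipitation (months
#' missing at any station propagate), at the mean station latitude. The
#' regional SPEI is computed from this pooled series.
#'
#' @param stations list of \code{\linkS4class{ClimateSeries}} on one
#'   month index.
#' @return a \code{\linkS4class{ClimateSeries}} with id \code{"REGION"}.
#' @export
regionalClimate <- function(stations) {
  ym <- monthIndex(stations[[1]])
  for (s in stations) stopifnot(identical(monthIndex(s), ym))
  tmp <- rowMeans(vapply(stations, temperature, numeric(length(ym))))
  pre <- rowMeans(vapply(stations, precipitation, numeric(length(ym))))
  climateSeries("REGION",
                mean(vapply(stations, function(s) s@latitude, 0)),
                mean(vapply(stations, function(s) s@longitude, 0)),
                mean(vapply(stations, function(s) s@elevation, 0)),
                ymYear(ym), ymMonth(ym), tmp, pre)
}

#' Simulate vegetation and landform masks
#'
#' Seeded multi-seed nearest-neighbour (Voronoi) patch allocation: each
#' class receives seed points in proportion to its target share and every
#' cell takes the class of its nearest seed, giving contiguous patches
#' with realized shares close to the targets.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return list of two \code{\linkS4class{CategoricalMask}}s: \code{veg}
#'   and \code{karst} (labels \code{K}, \code{NK}).
#' @export
simulateMasks <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(config$seed + 202L)
  ncell <- config$nrow * config$ncol
  voronoiMask <- function(shares, nSeeds) {
    if (ncell < length(shares))
      stop("domain too small for the requested classes")
    nSeeds <- max(length(shares), min(nSeeds, ncell %/% 12L))
    nPer <- pmax(1L, round(shares * nSeeds))
    cls <- rep(seq_along(shares), nPer)
    g <- gridSpec(config$nrow, config$ncol, config$cellsize)
    seeds <- cbind(stats::runif(length(cls), 0, config$ncol * config$cellsize),
                   stats::runif(length(cls), 0, config$nrow * config$cellsize))
    D <- .pairDist(g$xy, seeds)
    assign <- cls[max.col(-D, ties.method = "first")]
    matrix(as.integer(assign), config$nrow, config$ncol)
  }
  veg <- voronoiMask(config$vegShares, nSeeds = 250L)
  karst <- voronoiMask(c(K = config$karstShare, NK = 1 - config$karstShare),
                       nSeeds = 60L)
  list(
    veg = categoricalMask(veg, stats::setNames(names(config$vegShares),
                                               seq_along(config$vegShares))),
    karst = categoricalMask(karst, c("1" = "K", "2" = "NK")))
}

#' Simulate 16-day NDVI composites with a lagged drought response
#'
#' Per cell: a class seasonal curve (minimum January, peak July) plus
#' \code{sensitivity * min(0, SPEI lagged by responseLag)}, amplified on
#' karst cells, plus noise. Two composites per month (starting day 1 and
#' day 17) each suffer one-sided cloud suppression, so the monthly maximum
#' value composite recovers the underlying signal.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param spei either a \code{\linkS4class{SpeiSeries}} (regional series
#'   broadcast over the grid) or a \code{\linkS4class{MonthlyStack}} of
#'   gridded SPEI.
#' @param masks mask list from \code{\link{simulateMasks}}.
#' @return list: \code{composites} (rows x cols x n array),
#'   \code{dates} (composite start dates), \code{truth} (the noise-free
#'   monthly NDVI stack as a \code{MonthlyStack}).
#' @export
simulateNdvi <- function(config, spei, masks) {
  stopifnot(inherits(config, "ScenarioConfig"))
  set.seed(config$seed + 303L)
  if (is(spei, "SpeiSeries")) {
    ym <- monthIndex(spei)
    speiOf <- function(i) speiValues(spei)[i]   # scalar, broadcast
  } else {
    ym <- monthIndex(spei)
    speiOf <- function(i) spei@values[, , i]
  }
  nr <- config$nrow; nc <- config$ncol
  vcode <- maskValues(masks$veg)
  vlab <- maskLabels(masks$veg)[as.character(vcode)]
  if (!all(unique(vlab) %in% names(config$sensitivity)))
    stop("sensitivity table missing class(es): ",
         paste(setdiff(unique(vlab), names(config$sensitivity)),
               collapse = ", "))
  sens <- matrix(config$sensitivity[vlab], nr, nc)
  sens <- sens * ifelse(maskValues(masks$karst) == 1L,
                        config$karstAmplification, 1)
  meanM <- matrix(config$ndviMean[vlab], nr, nc)
  ampM <- matrix(config$ndviAmp[vlab], nr, nc)
  n <- length(ym)
  mon <- ymMonth(ym)
  lag <- config$responseLag
  truth <- array(NA_real_, c(nr, nc, n))
  comps <- array(NA_real_, c(nr, nc, 2L * n))
  dates <- rep(as.Date("2000-01-01"), 2L * n)
  for (i in seq_len(n)) {
    seasonal <- meanM + ampM * cos(2 * pi * (mon[i] - 7) / 12)
    resp <- 0
    if (i > lag) {
      sv <- speiOf(i - lag)
      sv[is.na(sv)] <- 0           # undefined index months: no response
      resp <- sens * pmin(0, sv)
    }
    tr <- pmin(1, pmax(-1, seasonal + resp))
    truth[, , i] <- tr
    for (j in 1:2) {
      obs <- tr - abs(stats::rnorm(nr * nc, 0, config$cloudSd)) +
        stats::rnorm(nr * nc, 0, config$ndviNoiseSd)
      comps[, , 2L * (i - 1L) + j] <- pmin(1, pmax(-1, obs))
      dates[2L * (i - 1L) + j] <- as.Date(sprintf(
        "%04d-%02d-%02d", ymYear(ym[i]), mon[i], c(1L, 17L)[j]))
    }
  }
  list(composites = comps, dates = dates,
       truth = monthlyStack(truth, ym = ym, varname = "NDVI",
                            cellsize = config$cellsize))
}

#' Simulate gridded hydrothermal variables
#'
#' TMP and PRE spread the regional station climate over the grid with
#' smooth spatial structure and noise; net shortwave radiation (SR) is a
#' seasonal curve anticorrelated with relative precipitation; surface (SM)
#' and root-zone (RM) soil moisture are AR(1) low-pass filters of the
#' standardized water balance squashed to volumetric [0, 1], the root zone
#' with the longer memory, so both decline with a lag during planted
#' droughts.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param climate a regional \code{\linkS4class{ClimateSeries}} (e.g. from
#'   \code{\link{regionalClimate}}).
#' @return named list of \code{\linkS4class{MonthlyStack}}s: \code{TMP}
#'   (degC), \code{PRE} (mm), \code{SR} (W m-2), \code{RM}, \code{SM}
#'   (volumetric fraction).
#' @export
simulateHydrothermal <- function(config, climate) {
  stopifnot(inherits(config, "ScenarioConfig"), is(climate, "ClimateSeries"))
  set.seed(config$seed + 404L)
  ym <- monthIndex(climate)
  n <- length(ym)
  mon <- ymMonth(ym)
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  # fixed smooth spatial pattern (west-east / north-south gradients)
  gx <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  gy <- matrix(rep(seq(-1, 1, length.out = nr), times = nc), nr, nc)
  spat <- 0.5 * gx + 0.3 * gy
  mkStack <- function(regional, spatScale, noiseSd, lo = -Inf, hi = Inf) {
    a <- array(NA_real_, c(nr, nc, n))
    for (i in seq_len(n))
      a[, , i] <- pmin(hi, pmax(lo, regional[i] + spatScale * spat +
                                  stats::rnorm(ncell, 0, noiseSd)))
    a
  }
  tmp <- climate@tmp
  pre <- climate@pre
  preClim <- stats::ave(pre, mon)
  relP <- pre / pmax(preClim, 1)
  sr <- 170 + 60 * cos(2 * pi * (mon - 7) / 12) - 40 * (relP - 1)
  wb <- pre - thornthwaitePet(tmp, mon, climate@latitude, ymYear(ym))
  wbz <- (wb - stats::ave(wb, mon)) / pmax(stats::ave(abs(wb), mon), 1)
  lp <- function(x, phi) {
    out <- numeric(length(x))
    out[1] <- x[1]
    for (t in 2:length(x)) out[t] <- phi * out[t - 1] + (1 - phi) * x[t]
    out
  }
  smSeason <- 0.05 * cos(2 * pi * (mon - 8) / 12)
  sm <- stats::plogis(0.8 + 1.2 * lp(wbz, 0.5)) * 0.5 + smSeason
  rm <- stats::plogis(1.0 + 1.0 * lp(wbz, 0.8)) * 0.5 + smSeason
  yl <- ymYear(ym[1])
  mk <- function(vals, varname, units, ...) {
    monthlyStack(mkStack(vals, ...), ym = ym, varname = varname,
                 units = units, cellsize = config$cellsize)
  }
  list(
    TMP = mk(tmp, "TMP", "degC", spatScale = 2, noiseSd = 0.4),
    PRE = mk(pre, "PRE", "mm", spatScale = 10, noiseSd = 6, lo = 0),
    SR = mk(sr, "SR", "W m-2", spatScale = 10, noiseSd = 5, lo = 0),
    RM = mk(rm, "RM", "frac", spatScale = 0.03, noiseSd = 0.01,
            lo = 0, hi = 1),
    SM = mk(sm, "SM", "frac", spatScale = 0.03, noiseSd = 0.015,
            lo = 0, hi = 1))
}

#' Run the full default synthetic scenario
#'
#' Climate -> regional SPEI -> events -> NDVI composites -> monthly MVC ->
#' drought-excluded baseline -> anomalies -> stratified summaries, plus
#' (optionally) the hydrothermal stacks. This is the end-to-end object the
#' package's examples and acceptance checks are built on.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param hydrothermal also simulate and summarize the hydrothermal grids
#'   (default \code{FALSE}; the NDVI pathway does not need them).
#' @return list with the intermediate products: \code{climate} (stations,
#'   xy, groundTruth), \code{regionalSpei}, \code{events}, \code{masks},
#'   \code{ndviMonthly}, \code{climatology}, \code{anomalies} (stacks),
#'   \code{droughtWindowSummary} (per-class mean anomalies over the
#'   detected drought months), \code{karstSummary}, and optionally
#'   \code{hydro}.
#' @export
simulateScenario <- function(config, hydrothermal = FALSE) {
  sim <- simulateClimate(config)
  reg <- regionalClimate(sim$stations)
  spei <- computeSpei(reg, k = config$k)
  events <- identifyEvents(spei, threshold = config$threshold)
  masks <- simulateMasks(config)
  ndvi <- simulateNdvi(config, spei, masks)
  monthly <- mvcMonthly(ndvi$composites, ndvi$dates,
                        cellsize = config$cellsize)
  emask <- eventMask(events, monthIndex(monthly))
  clim <- baselineClimatology(monthly, emask)
  an <- anomalyStack(monthly, clim)
  # per-class mean absolute anomaly over detected drought months
  droughtIdx <- which(emask)
  perClass <- NULL
  karstSummary <- NULL
  if (length(droughtIdx)) {
    meanAnom <- apply(an$absolute@values[, , droughtIdx, drop = FALSE],
                      c(1, 2), mean, na.rm = TRUE)
    perClass <- zonalSummary(meanAnom, masks$veg,
                             scope = "drought_months")
    karstSummary <- zonalSummary(meanAnom, masks$karst,
                                 excludeLabels = character(),
                                 scope = "drought_months")
  }
  out <- list(climate = sim, regionalSpei = spei, events = events,
              masks = masks, ndviMonthly = monthly, climatology = clim,
              anomalies = an, droughtWindowSummary = perClass,
              karstSummary = karstSummary)
  if (hydrothermal) {
    hyd <- simulateHydrothermal(config, reg)
    out$hydro <- hyd
    out$hydroSummary <- lapply(hyd, hydrothermalSummary,
                               droughtMask = emask)
  }
  out
}
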