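## Orchestration and IO: station CSV reading with the 5-percent
## missing-data exclusion rule, plain-text raster IO (ESRI ASCII grid),
## YAML configuration, and the end-to-end pipeline with a provenance
## report.

.STATION_HEADER <- c("station_id", "lat", "lon", "elev_m", "year",
                     "month", "tmp_c", "pre_mm")

#' Read station climate CSV with quality control
#'
#' Expects the header \code{station_id, lat, lon, elev_m, year, month,
#' tmp_c, pre_mm} with missing values as empty fields. A month is missing
#' if either variable is absent (or the row is absent); stations whose
#' missing fraction over the file's full month range exceeds
#' \code{maxMissingFraction} are excluded and logged. Duplicate
#' (station, year, month) rows are an error.
#'
#' @param path CSV file path.
#' @param maxMissingFraction exclusion threshold (default 0.05).
#' @return list: \code{stations} (list of
#'   \code{\linkS4class{ClimateSeries}}), \code{excluded} (data.frame
#'   \code{station_id}, \code{missing_fraction}), \code{meta} (per-station
#'   lat/lon/elev of retained stations).
#' @export
readStationCsv <- function(path, maxMissingFraction = 0.05) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0) stop("empty station file: ", path)
  hdr <- gsub('"', "", strsplit(hdr, ",")[[1]], fixed = TRUE)
  if (!identical(trimws(hdr), .STATION_HEADER))
    stop("header must be exactly: ", paste(.STATION_HEADER, collapse = ", "))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(station_id = "character")),
    error = function(e) stop("malformed station CSV: ", conditionMessage(e)))
  if (nrow(df) == 0) stop("empty station file: ", path)
  bad <- which(!df$month %in% 1:12 | is.na(df$year))
  if (length(bad))
    stop("malformed row(s) at line ", paste(bad + 1L, collapse = ", "),
         " (bad year/month)")
  key <- paste(df$station_id, df$year, df$month)
  if (anyDuplicated(key))
    stop("duplicate (station, year, month) rows at line ",
         paste(which(duplicated(key)) + 1L, collapse = ", "))
  df$ym <- ymCode(df$year, df$month)
  fullRange <- ymSeq(min(df$ym), max(df$ym))
  stations <- list()
  excluded <- data.frame(station_id = character(),
                         missing_fraction = numeric(),
                         stringsAsFactors = FALSE)
  meta <- list()
  for (id in unique(df$station_id)) {
    sub <- df[df$station_id == id, ]
    idx <- match(fullRange, sub$ym)
    tmp <- sub$tmp_c[idx]
    pre <- sub$pre_mm[idx]
    missFrac <- mean(is.na(tmp) | is.na(pre))
    if (missFrac > maxMissingFraction) {
      excluded <- rbind(excluded, data.frame(
        station_id = id, missing_fraction = missFrac,
        stringsAsFactors = FALSE))
      next
    }
    stations[[id]] <- climateSeries(
      id, sub$lat[1], sub$lon[1], sub$elev_m[1],
      ymYear(fullRange), ymMonth(fullRange), tmp, pre)
    meta[[id]] <- data.frame(station_id = id, lat = sub$lat[1],
                             lon = sub$lon[1], elev_m = sub$elev_m[1],
                             stringsAsFactors = FALSE)
  }
  list(stations = stations, excluded = excluded,
       meta = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' Write station climate CSV
#' @param stations list of \code{\linkS4class{ClimateSeries}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStationCsv <- function(stations, path) {
  rows <- lapply(stations, function(s) data.frame(
    station_id = s@stationId, lat = s@latitude, lon = s@longitude,
    elev_m = s@elevation, year = ymYear(s@ym), month = ymMonth(s@ym),
    tmp_c = s@tmp, pre_mm = s@pre, stringsAsFactors = FALSE))
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Plain-text raster IO (ESRI ASCII grid)
#'
#' Reads and writes single-band grids in the ESRI ASCII (.asc) format,
#' the package's text raster interchange format.
#'
#' @param m numeric matrix (row 1 = southern row; written north-up).
#' @param path file path.
#' @param cellsize,origin grid geometry (origin = lower-left corner).
#' @return \code{writeAsciiGrid}: \code{path} invisibly;
#'   \code{readAsciiGrid}: list \code{values}, \code{cellsize},
#'   \code{origin}.
#' @export
writeAsciiGrid <- function(m, path, cellsize = 250, origin = c(0, 0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", origin[1]), paste("yllcorner", origin[2]),
    paste("cellsize", cellsize), "NODATA_value -9999"), con)
  out <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  out[is.na(out)] <- -9999
  utils::write.table(format(out, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == h[["nodata_value"]]] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(values = m, cellsize = h[["cellsize"]],
       origin = c(h[["xllcorner"]], h[["yllcorner"]]))
}

#' Write an event table
#' @param events event table from \code{\link{identifyEvents}}.
#' @param csvPath,jsonPath output paths (either may be \code{NULL}).
#' @return invisibly, the paths written.
#' @export
writeEvents <- function(events, csvPath = NULL, jsonPath = NULL) {
  flat <- events[, setdiff(names(events), "month_classes")]
  if (!is.null(csvPath))
    utils::write.csv(flat, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    rep <- lapply(seq_len(nrow(events)), function(i) c(
      as.list(flat[i, ]),
      list(month_classes = as.list(stats::setNames(
        as.character(events$month_classes[[i]]),
        names(events$month_classes[[i]]))))))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(csvPath, jsonPath))
}

#' Default pipeline configuration
#'
#' All analysis constants surfaced in one validated list: SPEI timescale
#' k = 6, drought threshold -1.0, run-theory minimum duration 2 and merge
#' gap 1, meteorological season convention, interpolation settings and
#' reported strata.
#'
#' @param ... overrides of the defaults.
#' @return named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    paths = list(stations = NULL, ndviDir = NULL, hydroDir = NULL,
                 masksDir = NULL, outDir = "pipeline_out"),
    spei = list(k = 6L, threshold = -1.0, minDuration = 2L,
                mergeGap = 1L, calibration = NULL),
    interpolation = list(method = "kriging", idwPower = 2),
    strata = list(excludeLabels = "OTH"),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      sub <- dots[[nm]]
      unknownSub <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(unknownSub))
        stop("unknown key(s) in '", nm, "': ",
             paste(unknownSub, collapse = ", "))
      cfg[[nm]][names(sub)] <- sub
    } else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a YAML pipeline configuration
#' @param path YAML file; keys as in \code{\link{pipelineConfig}};
#'   unknown keys are rejected.
#' @return a validated \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline
#'
#' Station QC -> per-station and regional SPEI -> run-theory events ->
#' (optional) kriged SPEI surfaces for event peak months -> NDVI monthly
#' MVC -> drought-excluded baselines and anomalies -> stratified
#' summaries. Stages without configured inputs are skipped with a warning;
#' all outputs are written under \code{config$paths$outDir} and listed
#' with checksums in the returned report.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param scenario optional in-memory inputs as produced by the synthetic
#'   generators: list with \code{stations}, \code{xy} and optionally
#'   \code{ndvi} (composites + dates), \code{masks}. When given, file
#'   inputs are not read.
#' @return a RunReport list: \code{stages} (per-stage provenance),
#'   \code{events}, \code{summaries}, \code{warnings}, \code{files}
#'   (path + md5 checksum).
#' @export
runPipeline <- function(config, scenario = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  outDir <- config$paths$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), warnings = character(), files = list(),
                 seed = config$seed)
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(time = format(Sys.time()), ...)
  }
  warnlog <- function(msg) {
    report$warnings <<- c(report$warnings, msg)
    warning(msg, call. = FALSE)
  }
  ## stage: stations
  if (!is.null(scenario)) {
    stations <- scenario$stations
    excluded <- data.frame()
  } else if (!is.null(config$paths$stations)) {
    qc <- readStationCsv(config$paths$stations)
    stations <- qc$stations
    excluded <- qc$excluded
  } else stop("stage 'stations' failed: no station input configured")
  note("stations", nStations = length(stations),
       nExcluded = nrow(excluded))
  ## stage: spei + events
  reg <- regionalClimate(stations)
  spei <- computeSpei(reg, k = config$spei$k,
                      calibration = config$spei$calibration)
  events <- identifyEvents(spei, threshold = config$spei$threshold,
                           minDuration = config$spei$minDuration,
                           mergeGap = config$spei$mergeGap)
  speiCsv <- file.path(outDir, "spei6_regional.csv")
  utils::write.csv(data.frame(
    year = ymYear(monthIndex(spei)), month = ymMonth(monthIndex(spei)),
    spei6 = speiValues(spei),
    severity_class = as.character(classifySeverity(
      ifelse(is.na(speiValues(spei)), 0, speiValues(spei))))),
    speiCsv, row.names = FALSE)
  writeEvents(events, csvPath = file.path(outDir, "events.csv"),
              jsonPath = file.path(outDir, "events.json"))
  note("spei_events", k = config$spei$k,
       threshold = config$spei$threshold, nEvents = nrow(events))
  summaries <- list()
  ## stage: interpolation of the peak-month SPEI field
  xy <- if (!is.null(scenario)) scenario$xy else NULL
  if (!is.null(xy) && nrow(events)) {
    perStation <- lapply(stations, computeSpei, k = config$spei$k,
                         calibration = config$spei$calibration)
    iev <- which.min(events$peak_spei)       # strongest event's peak month
    peakYm <- events$onset[iev] + which.min(speiValues(spei)[
      match(ymSeq(events$onset[iev], events$termination[iev]),
            monthIndex(spei))]) - 1L
    vals <- vapply(perStation, function(s)
      speiValues(s)[match(peakYm, monthIndex(s))], numeric(1))
    st <- data.frame(x = xy$x, y = xy$y, value = vals)
    g <- gridSpec(60L, 60L, 250)
    fld <- if (identical(config$interpolation$method, "kriging")) {
      vg <- tryCatch(fitVariogram(st), error = function(e) NULL)
      if (is.null(vg)) idw(st, g, config$interpolation$idwPower)
      else ordinaryKriging(st, g, vg)$prediction
    } else idw(st, g, config$interpolation$idwPower)
    writeAsciiGrid(fld, file.path(outDir, sprintf(
      "spei6_%s.asc", ymLabel(peakYm))), g$cellsize, g$origin)
    note("interpolation", method = config$interpolation$method,
         month = ymLabel(peakYm))
  }
  ## stage: NDVI anomalies + stratification
  if (!is.null(scenario) && !is.null(scenario$ndvi)) {
    monthly <- mvcMonthly(scenario$ndvi$composites, scenario$ndvi$dates)
    emask <- eventMask(events, monthIndex(monthly))
    clim <- baselineClimatology(monthly, emask)
    an <- anomalyStack(monthly, clim)
    if (any(emask)) {
      meanAnom <- apply(an$absolute@values[, , emask, drop = FALSE],
                        c(1, 2), mean, na.rm = TRUE)
      if (!is.null(scenario$masks)) {
        summaries$byVeg <- zonalSummary(
          meanAnom, scenario$masks$veg,
          excludeLabels = config$strata$excludeLabels,
          scope = "drought_months")
        summaries$byLandform <- zonalSummary(
          meanAnom, scenario$masks$karst, excludeLabels = character(),
          scope = "drought_months")
        summaries$cross <- crossStratify(
          meanAnom, scenario$masks$veg, scenario$masks$karst,
          excludeVeg = config$strata$excludeLabels,
          scope = "drought_months")
        utils::write.csv(summaries$byVeg,
                         file.path(outDir, "anomaly_by_veg.csv"),
                         row.names = FALSE)
        utils::write.csv(summaries$byLandform,
                         file.path(outDir, "anomaly_by_landform.csv"),
                         row.names = FALSE)
      }
    }
    regSeries <- data.frame(
      month_label = ymLabel(monthIndex(monthly)),
      ndvi = regionalMeanSeries(monthly),
      anomaly = regionalMeanSeries(an$absolute))
    utils::write.csv(regSeries, file.path(outDir, "ndvi_regional.csv"),
                     row.names = FALSE)
    note("greenness", nMonths = length(monthIndex(monthly)),
         nDroughtMonths = sum(emask))
  } else {
    warnlog("no NDVI input configured: greenness stages skipped")
  }
  files <- list.files(outDir, full.names = TRUE)
  report$files <- data.frame(path = files,
                             md5 = unname(tools::md5sum(files)),
                             stringsAsFactors = FALSE)
  report$events <- events
  report$summaries <- summaries
  report
}
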