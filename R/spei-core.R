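## SPEI construction: Thornthwaite PET -> climatic water balance D = P - PET
## -> k-month rolling aggregation -> per-calendar-month 3-parameter
## log-logistic fit by unbiased probability-weighted moments -> standard
## normal quantile transform.

# mid-month Julian days used for the day-length correction
.MID_MONTH_J <- c(15L, 45L, 74L, 105L, 135L, 166L, 196L, 227L, 258L,
                  288L, 319L, 349L)
.DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L,
                    30L, 31L)

#' Monthly day-length correction factors
#'
#' Thornthwaite's correction K = (N/12) * (NDM/30), where N is mean day
#' length (hours) at the mid-month solar declination and NDM the number of
#' days in the month.
#'
#' @param latitude decimal degrees, in [-60, 60].
#' @return numeric length-12 correction factors, one per calendar month.
#' @export
dayLengthCorrection <- function(latitude) {
  stopifnot(length(latitude) == 1L, latitude >= -60, latitude <= 60)
  delta <- 0.4093 * sin(2 * pi * .MID_MONTH_J / 365 - 1.405)
  cosws <- pmin(1, pmax(-1, -tan(latitude * pi / 180) * tan(delta)))
  N <- 24 / pi * acos(cosws)
  (N / 12) * (.DAYS_IN_MONTH / 30)
}

#' Thornthwaite potential evapotranspiration
#'
#' Temperature-only monthly PET: the annual heat index
#' \eqn{I = \sum (t/5)^{1.514}} over the year's positive monthly means,
#' exponent \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 +
#' 1.792\times10^{-2} I + 0.49239}, uncorrected
#' \eqn{PET = 16 (10 t / I)^a} (with the standard quadratic for
#' t > 26.5 C), scaled by the day-length correction. PET is 0 for months
#' with mean temperature at or below freezing.
#'
#' @param tmp numeric monthly mean temperature (degrees C); \code{NA} allowed.
#' @param month calendar month (1-12) for each value.
#' @param latitude station latitude, decimal degrees in [-60, 60].
#' @param year optional calendar year per value; heat index is computed per
#'   year when given, otherwise from the long-term monthly means.
#' @return numeric PET (mm/month), \code{NA} where temperature is missing.
#' @examples
#' thornthwaitePet(rep(10, 12), 1:12, latitude = 0)
#' @export
thornthwaitePet <- function(tmp, month, latitude, year = NULL) {
  stopifnot(length(tmp) == length(month), all(month %in% 1:12))
  K <- dayLengthCorrection(latitude)
  tpos <- pmax(tmp, 0)
  grp <- if (is.null(year)) rep(1L, length(tmp)) else as.integer(year)
  pet <- rep(NA_real_, length(tmp))
  for (g in unique(grp)) {
    sel <- grp == g
    # heat index from this group's monthly means (one value per calendar month)
    mt <- tapply(tpos[sel], month[sel], mean, na.rm = TRUE)
    mt[!is.finite(mt)] <- NA
    if (all(is.na(mt))) next   # all-missing year: PET stays NA, flagged
    I <- sum((mt / 5)^1.514, na.rm = TRUE)
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    t <- tmp[sel]
    m <- month[sel]
    u <- ifelse(t <= 0, 0,
         ifelse(t < 26.5,
                if (I > 0) 16 * (10 * t / I)^a else 0,
                -415.85 + 32.24 * t - 0.43 * t^2))
    pet[sel] <- pmax(u, 0) * K[m]
  }
  pet[is.na(tmp)] <- NA_real_
  pet
}

#' Climatic water balance
#'
#' \code{d = p - pet}; missing values propagate.
#'
#' @param p,pet numeric monthly series sharing one month index.
#' @param ym optional integer ym codes used in error messages.
#' @return numeric difference series.
#' @export
waterBalance <- function(p, pet, ym = NULL) {
  if (length(p) != length(pet)) {
    off <- if (!is.null(ym)) paste(":", paste(ymLabel(ym), collapse = ", "))
           else ""
    stop("p and pet month indices differ in length", off)
  }
  p - pet
}

#' k-month rolling aggregation
#'
#' \code{dk[m] = sum(d[(m-k+1):m])}; the first \code{k - 1} months and any
#' window containing a missing value are \code{NA}.
#'
#' @param d numeric monthly series.
#' @param k aggregation timescale (months), >= 1.
#' @return numeric series of the same length.
#' @export
aggregateK <- function(d, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- length(d)
  if (k > n) {
    warning("aggregation window k = ", k, " exceeds series length ", n)
    return(numeric(0))
  }
  if (k == 1L) return(d)
  # cumulative sums with NA propagation inside each window
  dk <- rep(NA_real_, n)
  x <- ifelse(is.na(d), 0, d)
  cs <- cumsum(x)
  bad <- cumsum(is.na(d))
  idx <- k:n
  tot <- cs[idx] - c(0, cs)[idx - k + 1L]
  nbad <- bad[idx] - c(0, bad)[idx - k + 1L]
  dk[idx] <- ifelse(nbad > 0, NA_real_, tot)
  dk
}

# unbiased probability-weighted moments b0, b1, b2 of a sample
.pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((j - 1) / (n - 1) * x) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * x) / n
  c(b0 = b0, b1 = b1, b2 = b2)
}

#' Fit a three-parameter log-logistic distribution by unbiased PWMs
#'
#' The canonical SPEI fit, expressed in unbiased b-type PWMs
#' \eqn{b_s = E[X F(X)^s]}: shape
#' \eqn{\beta = (b_0 - 2 b_1) / (6 b_1 - b_0 - 6 b_2)}, scale
#' \eqn{\alpha = (2 b_1 - b_0)\beta / (\Gamma(1 + 1/\beta)\Gamma(1 - 1/\beta))},
#' origin \eqn{\gamma = b_0 - \alpha \Gamma(1 + 1/\beta)\Gamma(1 - 1/\beta)},
#' with CDF \eqn{F(x) = [1 + (\alpha/(x - \gamma))^\beta]^{-1}}.
#'
#' A sample whose third L-moment is negative (left skew, possible in short
#' calibration samples) has no valid log-logistic shape; such samples are
#' fitted on their reflection \code{-x} and the CDF flipped, preserving a
#' proper monotone fit.
#'
#' @param x numeric sample (one calendar month's aggregated water balances);
#'   at least 10 non-missing, not all equal.
#' @return list with \code{alpha}, \code{beta}, \code{gamma}, \code{n},
#'   the PWMs in \code{lmom}, and \code{reflected} (TRUE if fitted on
#'   \code{-x}).
#' @export
fitLogLogisticPwm <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 10L)
    stop("need at least 10 non-missing samples; extend the calibration period")
  if (diff(range(x)) == 0)
    stop("degenerate (constant) sample: log-logistic fit undefined")
  fit1 <- function(x, reflected) {
    b <- .pwm(x)
    beta <- (b["b0"] - 2 * b["b1"]) / (6 * b["b1"] - b["b0"] - 6 * b["b2"])
    if (!is.finite(beta) || beta <= 1) return(NULL)
    g12 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
    alpha <- (2 * b["b1"] - b["b0"]) * beta / g12
    gam <- b["b0"] - alpha * g12
    list(alpha = unname(alpha), beta = unname(beta), gamma = unname(gam),
         n = length(x), lmom = unname(b), reflected = reflected)
  }
  out <- fit1(x, FALSE)
  if (is.null(out)) out <- fit1(-x, TRUE)
  if (is.null(out))
    stop("log-logistic shape estimate out of range (beta <= 1)")
  out
}

#' Log-logistic CDF
#' @param x quantiles.
#' @param params a fit from \code{\link{fitLogLogisticPwm}}.
#' @return probabilities in [0, 1]; values at or below the origin (at or
#'   above it for a reflected fit) map to the corresponding tail.
#' @export
pLogLogistic <- function(x, params) {
  if (isTRUE(params$reflected)) x <- -x
  z <- x - params$gamma
  p <- ifelse(z <= 0, 0, 1 / (1 + (params$alpha / z)^params$beta))
  if (isTRUE(params$reflected)) 1 - p else p
}

#' Log-logistic quantile function
#' @param p probabilities in (0, 1).
#' @param params a fit from \code{\link{fitLogLogisticPwm}}.
#' @return quantiles.
#' @export
qLogLogistic <- function(p, params) {
  if (isTRUE(params$reflected)) p <- 1 - p
  q <- params$gamma + params$alpha * (p / (1 - p))^(1 / params$beta)
  if (isTRUE(params$reflected)) -q else q
}

#' Standardize aggregated water balances to SPEI
#'
#' Maps each defined \code{dk} through its calendar month's fitted CDF and
#' the standard normal quantile. Probabilities are clipped to
#' \code{[1e-6, 1 - 1e-6]} before the quantile so tail values (including
#' \code{dk} at or below the fitted origin) stay finite.
#'
#' @param dk numeric aggregated series.
#' @param month calendar month (1-12) per value.
#' @param paramsByMonth list of 12 fits (January first).
#' @return numeric SPEI values, \code{NA} exactly where \code{dk} is
#'   \code{NA}.
#' @export
standardizeSpei <- function(dk, month, paramsByMonth) {
  stopifnot(length(paramsByMonth) == 12L)
  if (any(vapply(paramsByMonth, is.null, logical(1))))
    stop("parameters must be fitted for all 12 calendar months")
  out <- rep(NA_real_, length(dk))
  for (m in 1:12) {
    sel <- month == m & !is.na(dk)
    if (!any(sel)) next
    p <- pLogLogistic(dk[sel], paramsByMonth[[m]])
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    out[sel] <- stats::qnorm(p)
  }
  out
}

#' Compute an SPEI series from station climate
#'
#' Full construction: Thornthwaite PET, water balance, k-month aggregation,
#' per-calendar-month PWM log-logistic fit over the calibration period,
#' normal-quantile standardization.
#'
#' @param climate a \code{\linkS4class{ClimateSeries}}.
#' @param k timescale in months (default 6).
#' @param calibration optional integer length-2 ym range for fitting;
#'   defaults to the full record.
#' @return a \code{\linkS4class{SpeiSeries}}.
#' @examples
#' cl <- simulateClimate(scenarioConfig(seed = 1))$stations[[1]]
#' sp <- computeSpei(cl, k = 6)
#' summary(speiValues(sp))
#' @export
computeSpei <- function(climate, k = 6L, calibration = NULL) {
  stopifnot(is(climate, "ClimateSeries"))
  ym <- climate@ym
  mon <- ymMonth(ym)
  pet <- thornthwaitePet(climate@tmp, mon, climate@latitude,
                         year = ymYear(ym))
  d <- waterBalance(climate@pre, pet, ym)
  dk <- aggregateK(d, k)
  if (is.null(calibration)) calibration <- range(ym)
  calib <- ym >= calibration[1] & ym <= calibration[2]
  params <- vector("list", 12L)
  for (m in 1:12) {
    samp <- dk[calib & mon == m]
    params[[m]] <- fitLogLogisticPwm(samp)
  }
  spei <- standardizeSpei(dk, mon, params)
  new("SpeiSeries", ym = ym, spei = spei, k = as.integer(k),
      params = params, calibration = as.integer(calibration))
}

.SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe", "extreme")

#' Classify SPEI drought severity
#'
#' National meteorological drought rating: mild (-1.0, -0.5], moderate
#' (-1.5, -1.0], severe (-2.0, -1.5], extreme (-Inf, -2.0]; above -0.5 is
#' "none". Boundaries belong to the drier class.
#'
#' @param spei finite numeric values.
#' @return ordered factor with levels none < mild < moderate < severe <
#'   extreme.
#' @examples
#' classifySeverity(c(-0.4, -0.7, -1.2, -1.78, -2.3))
#' @export
classifySeverity <- function(spei) {
  if (any(!is.finite(spei)))
    stop("severity classification requires finite SPEI values")
  cls <- cut(spei, breaks = c(-Inf, -2.0, -1.5, -1.0, -0.5, Inf),
             labels = c("extreme", "severe", "moderate", "mild", "none"),
             right = TRUE)
  factor(as.character(cls), levels = .SEVERITY_LEVELS, ordered = TRUE)
}
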