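test_that("month index round-trips and stays contiguous", {
  ym <- ymCode(2009, 10) + 0:7
  expect_identical(ymYear(ym[1]), 2009L)
  expect_identical(ymMonth(ym), c(10:12, 1:5))
  expect_identical(ymLabel(ym[8]), "2010-05")
  expect_error(climateSeries("X", 26, 106, 1000, c(2001, 2001), c(1, 3),
                             c(5, 6), c(10, 10)),
               "contiguous")
  expect_error(climateSeries("X", 26, 106, 1000, 2001, 1, 5, -3),
               "non-negative")
})

test_that("Thornthwaite PET freezing branch, oracle agreement, day-length scaling", {
  # mean temperature at or below 0 C gives zero PET
  pet <- thornthwaitePet(c(-5, rep(10, 11)), 1:12, latitude = 26)
  expect_identical(pet[1], 0)
  expect_true(all(pet >= 0))

  # uniform 10 C at the equator matches the independently scripted formula
  pet0 <- thornthwaitePet(rep(10, 12), 1:12, latitude = 0)
  expect_equal(pet0, oracleThornthwaite(rep(10, 12), 0), tolerance = 1e-9)

  # random years and latitudes agree with the scalar oracle
  set.seed(71)
  for (i in 1:10) {
    t12 <- runif(12, -3, 30)
    lat <- runif(1, -55, 55)
    expect_equal(thornthwaitePet(t12, 1:12, lat),
                 oracleThornthwaite(t12, lat), tolerance = 1e-9)
  }

  # PET is linear in the day-length correction factor: for uniform
  # temperature, PET / K is constant across months
  K <- dayLengthCorrection(40)
  petU <- thornthwaitePet(rep(18, 12), 1:12, latitude = 40)
  expect_equal(max(petU / K) - min(petU / K), 0, tolerance = 1e-9)

  # all-missing year stays missing
  expect_true(all(is.na(thornthwaitePet(rep(NA_real_, 12), 1:12, 26,
                                        year = rep(2001, 12)))))
  expect_error(thornthwaitePet(rep(10, 12), 1:12, latitude = 75))
})

test_that("water balance is p - pet with propagation and index checking", {
  expect_equal(waterBalance(c(50, 60), c(40, 80)), c(10, -20))
  expect_equal(waterBalance(c(10, 10), c(10, 10)), c(0, 0))
  expect_true(is.na(waterBalance(c(NA, 5), c(1, 1))[1]))
  expect_error(waterBalance(1:3, 1:2), "differ")
})

test_that("k-month aggregation matches the rolling-sum oracle", {
  expect_equal(aggregateK(c(1, 2, 3, 4), 2), c(NA, 3, 5, 7))
  expect_equal(aggregateK(c(5, 1), 1), c(5, 1))
  expect_equal(aggregateK(rep(2, 10), 6)[6:10], rep(12, 5))
  expect_warning(out <- aggregateK(1:3, 5), "exceeds")
  expect_length(out, 0)
  set.seed(72)
  for (i in 1:10) {
    d <- rnorm(40)
    d[sample(40, 3)] <- NA
    k <- sample(2:8, 1)
    expect_equal(aggregateK(d, k), oracleRollSum(d, k), tolerance = 1e-9)
  }
})

test_that("PWM log-logistic fit recovers known parameters and the sample CDF", {
  set.seed(1)
  n <- 1000
  u <- (sample(n) - 1 + runif(n)) / n   # stratified draw, no luck variance
  x <- oracleQll(u, alpha = 50, beta = 3, gam = 100)
  fit <- fitLogLogisticPwm(x)
  expect_lt(abs(fit$alpha - 50) / 50, 0.10)
  expect_lt(abs(fit$beta - 3) / 3, 0.10)
  expect_lt(abs(fit$gamma - 100) / 100, 0.10)

  # fitted CDF vs the empirical CDF of the fitting sample
  xs <- sort(x)
  ks <- max(abs(pLogLogistic(xs, fit) - seq_along(xs) / n))
  expect_lt(ks, 0.1)

  # CDF at the sample median near one half
  expect_gt(pLogLogistic(median(x), fit), 0.4)
  expect_lt(pLogLogistic(median(x), fit), 0.6)

  # location equivariance: shifting the sample shifts only the origin
  fit2 <- fitLogLogisticPwm(x + 37)
  expect_equal(fit2$gamma, fit$gamma + 37, tolerance = 1e-6)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-9)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-9)

  expect_error(fitLogLogisticPwm(rep(3, 20)), "degenerate")
  expect_error(fitLogLogisticPwm(1:5), "at least 10")
})

test_that("left-skewed samples are fitted on their reflection", {
  set.seed(2)
  u <- (sample(500) - 1 + runif(500)) / 500
  x <- -oracleQll(u, alpha = 30, beta = 3, gam = 0)   # left-skewed
  fit <- fitLogLogisticPwm(x)
  expect_true(fit$reflected)
  xs <- sort(x)
  expect_lt(max(abs(pLogLogistic(xs, fit) - seq_along(xs) / 500)), 0.1)
  # still strictly nondecreasing
  expect_true(all(diff(pLogLogistic(xs, fit)) >= 0))
})

test_that("standardization maps the fitted median to zero and is monotone", {
  set.seed(3)
  params <- lapply(1:12, function(m) {
    u <- (sample(200) - 1 + runif(200)) / 200
    fitLogLogisticPwm(oracleQll(u, 40 + m, 2.5, 50 * m))
  })
  med <- vapply(params, function(p) qLogLogistic(0.5, p), numeric(1))
  z <- standardizeSpei(med, 1:12, params)
  expect_equal(z, rep(0, 12), tolerance = 1e-6)

  # monotone within a calendar month, and finite at the tails
  xs <- seq(-500, 5000, length.out = 200)
  zs <- standardizeSpei(xs, rep(4, 200), params)
  expect_true(all(diff(zs) >= 0))
  expect_true(all(is.finite(zs)))
  expect_equal(min(zs), qnorm(1e-6))

  expect_error(standardizeSpei(1, 1, params[1:11]))
})

test_that("SPEI is self-calibrated on a 21-year record", {
  cfg <- scenarioConfig(seed = 11, droughts = list(), nStations = 1L)
  st <- simulateClimate(cfg)$stations[[1]]
  sp <- computeSpei(st, k = 6)
  v <- speiValues(sp)
  expect_identical(which(is.na(v)), 1:5)   # first k-1 months undefined
  mon <- ymMonth(monthIndex(sp))
  m <- tapply(v, mon, mean, na.rm = TRUE)
  s <- tapply(v, mon, sd, na.rm = TRUE)
  expect_true(all(abs(m) <= 0.1))
  expect_true(all(s >= 0.85 & s <= 1.15))
})

test_that("standardize-after-fit is invariant to a per-month location shift", {
  cl <- toyClimate(years = 21)
  set.seed(4)
  pre <- precipitation(cl) * exp(rnorm(length(cl@ym), 0, 0.3))
  mon <- ymMonth(monthIndex(cl))
  pet <- thornthwaitePet(temperature(cl), mon, cl@latitude,
                         ymYear(monthIndex(cl)))
  dk <- aggregateK(waterBalance(pre, pet), 6)
  fitSPEI <- function(dk) {
    params <- lapply(1:12, function(m) fitLogLogisticPwm(dk[mon == m]))
    standardizeSpei(dk, mon, params)
  }
  dk2 <- dk + ifelse(mon == 7, 250, 0)    # shift one calendar month
  expect_equal(fitSPEI(dk), fitSPEI(dk2), tolerance = 1e-6)
})

test_that("severity classes partition the line exactly as the rating table", {
  eps <- 1e-9
  sweep <- c(-0.5, -0.5 - eps, -1.0, -1.0 - eps, -1.5, -1.5 - eps,
             -2.0, -2.0 - eps)
  expect_identical(as.character(classifySeverity(sweep)),
                   c("mild", "mild", "moderate", "moderate",
                     "severe", "severe", "extreme", "extreme"))
  expect_identical(as.character(classifySeverity(-1.78)), "severe")
  expect_identical(as.character(classifySeverity(-0.4)), "none")
  expect_identical(as.character(classifySeverity(3)), "none")
  # every finite value maps to exactly one ordered class
  set.seed(5)
  x <- runif(1000, -5, 3)
  cls <- classifySeverity(x)
  expect_false(anyNA(cls))
  expect_true(is.ordered(cls))
  expect_error(classifySeverity(c(-1, NA)), "finite")
  expect_error(classifySeverity(Inf), "finite")
})

test_that("computeSpei carries its parameters and calibration window", {
  cfg <- scenarioConfig(seed = 12, droughts = list(), nStations = 1L)
  st <- simulateClimate(cfg)$stations[[1]]
  sp <- computeSpei(st, k = 6, calibration = c(ymCode(2001, 1),
                                               ymCode(2015, 12)))
  expect_length(sp@params, 12)
  expect_identical(sp@calibration, c(ymCode(2001, 1), ymCode(2015, 12)))
  expect_identical(sp@k, 6L)
})
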