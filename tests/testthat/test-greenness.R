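test_that("monthly MVC takes per-cell maxima and ignores missing composites", {
  a <- array(c(0.31, 0.47), c(1, 1, 2))
  out <- mvcMonthly(a, as.Date(c("2010-01-01", "2010-01-17")))
  expect_equal(as.vector(stackValues(out)), 0.47)

  # single composite is the identity
  b <- array(0.25, c(2, 2, 1))
  expect_equal(stackValues(mvcMonthly(b, as.Date("2010-03-01")))[, , 1],
               matrix(0.25, 2, 2))

  # missing composite values are ignored; all-missing stays missing
  cc <- array(c(NA, 0.2, NA, NA), c(1, 1, 4))
  out <- mvcMonthly(cc, as.Date(c("2010-01-01", "2010-01-17",
                                  "2010-02-01", "2010-02-17")))
  expect_equal(stackValues(out)[1, 1, ], c(0.2, NA))

  # a month with no composites is an all-NA layer with a warning
  expect_warning(
    gap <- mvcMonthly(array(0.3, c(1, 1, 2)),
                      as.Date(c("2010-01-01", "2010-03-01"))),
    "no assigned composites")
  expect_true(all(is.na(stackValues(gap)[, , 2])))
  expect_identical(length(monthIndex(gap)), 3L)

  # MVC output dominates every contributing composite cellwise
  set.seed(31)
  r <- array(runif(4 * 5 * 8, -0.2, 0.9), c(4, 5, 8))
  dts <- as.Date(c("2011-06-01", "2011-06-09", "2011-06-17", "2011-06-25",
                   "2011-07-01", "2011-07-09", "2011-07-17", "2011-07-25"))
  mv <- stackValues(mvcMonthly(r, dts))
  for (j in 1:4) expect_true(all(mv[, , 1] >= r[, , j]))
  for (j in 5:8) expect_true(all(mv[, , 2] >= r[, , j]))
})

test_that("baseline climatology excludes drought months and counts years", {
  set.seed(32)
  nyears <- 21
  vals <- array(rnorm(3 * 3 * 12 * nyears, 0.5, 0.1),
                c(3, 3, 12 * nyears))
  stk <- monthlyStack(vals, year = rep(2001:2021, each = 12),
                      month = rep(1:12, nyears))
  ym <- monthIndex(stk)

  # without a mask the baseline is the plain multi-year mean
  clim0 <- baselineClimatology(stk)
  octIdx <- which(ymMonth(ym) == 10)
  expect_equal(clim0@baseline[, , 10],
               apply(vals[, , octIdx], c(1, 2), mean), tolerance = 1e-12)
  expect_identical(clim0@nContrib, rep(21L, 12))

  # masking two Octobers leaves the mean of the other 19
  mask <- rep(FALSE, length(ym))
  mask[octIdx[c(3, 7)]] <- TRUE
  clim <- baselineClimatology(stk, mask)
  expect_identical(clim@nContrib[10], 19L)
  expect_equal(clim@baseline[, , 10],
               apply(vals[, , octIdx[-c(3, 7)]], c(1, 2), mean),
               tolerance = 1e-12)
  expect_identical(clim@excluded, ym[mask])

  # constant series: baseline equals the constant under any mask
  cvals <- array(0.4, c(2, 2, 24))
  cstk <- monthlyStack(cvals, year = rep(2001:2002, each = 12),
                       month = rep(1:12, 2))
  cmask <- c(rep(TRUE, 12), rep(FALSE, 12))   # first year excluded
  expect_equal(as.vector(baselineClimatology(cstk, cmask)@baseline),
               rep(0.4, 48))

  # every year masked: missing unless the all-years fallback is on
  allmask <- ymMonth(ym) == 3
  climNA <- baselineClimatology(stk, allmask)
  expect_true(all(is.na(climNA@baseline[, , 3])))
  expect_identical(climNA@nContrib[3], 0L)
  climFB <- baselineClimatology(stk, allmask, fallbackAllYears = TRUE)
  expect_false(anyNA(climFB@baseline[, , 3]))
})

test_that("anomalies follow the sign convention and printed-pair consistency", {
  a <- anomaly(0.45, 0.50)
  expect_equal(a$absolute, -0.05)
  expect_equal(a$percent, -10)
  expect_equal(anomaly(0.3, 0.3), list(absolute = 0, percent = 0))

  # the printed NDVI pair (-0.16, -28.54%) back-implies its baseline;
  # forward evaluation reproduces both numbers at 2 decimals
  baseline <- 0.16 / 0.2854
  obs <- baseline - 0.16
  a <- anomaly(obs, baseline)
  expect_equal(round(a$absolute, 2), -0.16)
  expect_equal(round(a$percent, 2), -28.54)

  # percent undefined below the baseline floor; absolute still reported
  tiny <- anomaly(0.004, 0.005)
  expect_true(is.na(tiny$percent))
  expect_equal(tiny$absolute, -0.001)

  # antisymmetry of the absolute anomaly
  set.seed(33)
  x <- runif(20); y <- runif(20)
  expect_equal(anomaly(x, y)$absolute, -anomaly(y, x)$absolute)

  # sign consistency where the baseline is positive
  p <- anomaly(x, y + 1)
  expect_true(all(sign(p$percent) == sign(p$absolute) |
                    p$absolute == 0))
  expect_error(anomaly(1:3, 1:2), "share")
})

test_that("per-month mean anomaly over contributing years is zero", {
  set.seed(34)
  nyears <- 10
  vals <- array(runif(2 * 2 * 12 * nyears, 0.2, 0.9),
                c(2, 2, 12 * nyears))
  stk <- monthlyStack(vals, year = rep(2001:2010, each = 12),
                      month = rep(1:12, nyears))
  mask <- runif(12 * nyears) < 0.2
  clim <- baselineClimatology(stk, mask)
  an <- anomalyStack(stk, clim)
  mon <- ymMonth(monthIndex(stk))
  for (m in 1:12) {
    sel <- which(mon == m & !mask)
    resid <- apply(an$absolute@values[, , sel, drop = FALSE],
                   c(1, 2), mean)
    expect_true(all(abs(resid) < 1e-9))
  }
})

test_that("seasonal anomalies average member months against the season baseline", {
  ym <- ymCode(rep(2010, 12), 1:12)
  absAnom <- rep(0, 12); base <- rep(0.5, 12)
  absAnom[3:5] <- -0.06
  out <- seasonalAnomaly(absAnom, base, ym, "spring", 2010)
  expect_equal(out$absolute, -0.06)
  expect_equal(out$percent, 100 * -0.06 / 0.5)

  absAnom[6:8] <- c(0.1, -0.1, 0)
  expect_equal(seasonalAnomaly(absAnom, base, ym, "summer", 2010)$absolute, 0)

  expect_warning(
    out <- seasonalAnomaly(absAnom, base, ym, "winter", 2010), "missing")
  expect_true(is.na(out$absolute))
})

test_that("minimum shift is signed, zero for identical curves, ties flagged", {
  base <- c(10, 11, 12, 14, 16, 18, 20, 19, 17, 15, 13, 11)
  obs <- base; obs[1] <- 12; obs[3] <- 10    # minimum moved Jan -> Mar
  expect_identical(as.integer(minimumShift(obs, base)), 2L)
  expect_identical(as.integer(minimumShift(base, base)), 0L)
  obs2 <- base; obs2[2] <- 9                  # one month ahead of Feb? no:
  # baseline min is Jan; obs2 min is Feb -> +1; check the -1 direction too
  expect_identical(as.integer(minimumShift(obs2, base)), 1L)
  base2 <- c(5, 4, 3, 4, 5, 6, 7, 8, 7, 6, 5, 4)   # min in Mar
  obs3 <- c(5, 3, 4, 4, 5, 6, 7, 8, 7, 6, 5, 4)    # min in Feb
  expect_identical(as.integer(minimumShift(obs3, base2)), -1L)
  tied <- minimumShift(c(1, 1, rep(2, 10)), base2)
  expect_true(attr(tied, "ties"))
  expect_error(minimumShift(1:11, base2))
})

test_that("regional mean series averages valid cells with equal weight", {
  vals <- array(c(1, 2, 3, NA), c(2, 2, 1))
  stk <- monthlyStack(vals, year = 2010, month = 1, varname = "PRE",
                      units = "mm")
  expect_equal(unname(regionalMeanSeries(stk)), 2)
  expect_identical(names(regionalMeanSeries(stk)), "2010-01")
})
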