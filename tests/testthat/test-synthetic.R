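smallCfg <- function(seed, ...) {
  scenarioConfig(seed = seed, nrow = 10L, ncol = 10L, nStations = 6L, ...)
}

test_that("generators are bit-identical under a fixed seed", {
  c1 <- smallCfg(9)
  a <- simulateClimate(c1); b <- simulateClimate(c1)
  expect_identical(lapply(a$stations, precipitation),
                   lapply(b$stations, precipitation))
  expect_identical(a$xy, b$xy)
  m1 <- simulateMasks(c1); m2 <- simulateMasks(c1)
  expect_identical(maskValues(m1$veg), maskValues(m2$veg))
  expect_identical(maskValues(m1$karst), maskValues(m2$karst))
  sp <- computeSpei(regionalClimate(a$stations))
  n1 <- simulateNdvi(c1, sp, m1); n2 <- simulateNdvi(c1, sp, m1)
  expect_identical(n1$composites, n2$composites)
  h1 <- simulateHydrothermal(c1, regionalClimate(a$stations))
  h2 <- simulateHydrothermal(c1, regionalClimate(a$stations))
  expect_identical(stackValues(h1$SM), stackValues(h2$SM))
  expect_error(scenarioConfig(), "seed")
})

test_that("simulated climate is a monsoon regime with the planted deficit", {
  cfg <- smallCfg(10)
  sim <- simulateClimate(cfg)
  for (s in sim$stations) {
    expect_true(all(precipitation(s) >= 0))
    expect_false(anyNA(precipitation(s)))
  }
  # roughly 80 percent of annual precipitation falls April-October
  reg <- regionalClimate(sim$stations)
  mon <- ymMonth(monthIndex(reg))
  yr <- ymYear(monthIndex(reg))
  normalYears <- setdiff(unique(yr), 2011:2012)
  wet <- sum(precipitation(reg)[mon %in% 4:10 & yr %in% normalYears])
  tot <- sum(precipitation(reg)[yr %in% normalYears])
  expect_gt(wet / tot, 0.72)
  expect_lt(wet / tot, 0.92)
  # winter around 5 C, summer around 24 C
  expect_lt(mean(temperature(reg)[mon == 1]), 9)
  expect_gt(mean(temperature(reg)[mon == 7]), 20)
  expect_warning(simulateClimate(scenarioConfig(seed = 1, years = 10L)),
                 "unstable")
})

test_that("the planted deficit depresses drought-window precipitation", {
  # under a strong multiplier the station-mean precipitation inside the
  # forcing window sits below the same-months climatology in nearly all
  # seeds
  hits <- 0
  for (s in 1:100) {
    cfg <- scenarioConfig(seed = s, nrow = 4L, ncol = 4L, nStations = 4L,
      droughts = list(list(startYear = 2011L, startMonth = 5L,
                           months = 8L, preMultiplier = 0.4,
                           tmpOffset = 1)))
    sim <- simulateClimate(cfg)
    reg <- regionalClimate(sim$stations)
    ym <- monthIndex(reg); mon <- ymMonth(ym)
    win <- sim$groundTruth$forcingWindows[[1]]
    inWin <- ym %in% win
    clim <- tapply(precipitation(reg)[!inWin], mon[!inWin], mean)
    hits <- hits + (mean(precipitation(reg)[inWin]) <
                      mean(clim[as.character(ymMonth(win))]))
  }
  expect_gte(hits, 95)
})

test_that("masks label every cell with shares near the targets", {
  cfg <- scenarioConfig(seed = 13)
  masks <- simulateMasks(cfg)
  vals <- maskValues(masks$veg)
  expect_false(anyNA(vals))
  expect_false(anyNA(maskValues(masks$karst)))
  share <- table(factor(vals, levels = 1:6)) / length(vals)
  expect_true(all(abs(share - cfg$vegShares) <= 0.05))
  kshare <- mean(maskValues(masks$karst) == 1L)
  expect_lt(abs(kshare - cfg$karstShare), 0.05)
  expect_setequal(unname(maskLabels(masks$veg)),
                  c("BDF", "NDF", "SCR", "MDW", "GRA", "OTH"))
  expect_error(simulateMasks(scenarioConfig(seed = 1, nrow = 2L, ncol = 2L)),
               "too small")
})

test_that("NDVI stacks respond to SPEI only through the planted sensitivity", {
  cfg <- smallCfg(14, sensitivity = c(BDF = 0, NDF = 0, SCR = 0,
                                      MDW = 0, GRA = 0, OTH = 0))
  sim <- simulateClimate(cfg)
  sp <- computeSpei(regionalClimate(sim$stations))
  masks <- simulateMasks(cfg)
  nd <- simulateNdvi(cfg, sp, masks)
  monthly <- mvcMonthly(nd$composites, nd$dates)
  # regional NDVI anomaly is uncorrelated with SPEI when sensitivity is 0
  clim <- baselineClimatology(monthly)
  an <- anomalyStack(monthly, clim)
  reg <- unname(regionalMeanSeries(an$absolute))
  v <- speiValues(sp)
  ok <- !is.na(v)
  expect_lt(abs(cor(reg[ok], v[ok])), 0.1)
  expect_true(all(abs(stackValues(monthly)) <= 1, na.rm = TRUE))

  # with sensitivities on, the MVC recovers the noise-free signal closely
  cfg2 <- smallCfg(14)
  nd2 <- simulateNdvi(cfg2, sp, masks)
  monthly2 <- mvcMonthly(nd2$composites, nd2$dates)
  err <- stackValues(monthly2) - stackValues(nd2$truth)
  expect_lt(mean(abs(err)), 0.05)
  expect_error(
    simulateNdvi(smallCfg(14, sensitivity = c(BDF = 0.1)), sp, masks),
    "missing class")
})

test_that("hydrothermal stacks respect units, bounds and drought depletion", {
  cfg <- smallCfg(15)
  reg <- regionalClimate(simulateClimate(cfg)$stations)
  hyd <- simulateHydrothermal(cfg, reg)
  expect_identical(names(hyd), c("TMP", "PRE", "SR", "RM", "SM"))
  expect_true(all(stackValues(hyd$SM) >= 0 & stackValues(hyd$SM) <= 1))
  expect_true(all(stackValues(hyd$RM) >= 0 & stackValues(hyd$RM) <= 1))
  expect_identical(hyd$SR@units, "W m-2")

  # shortwave radiation is anticorrelated with relative precipitation
  mon <- ymMonth(monthIndex(reg))
  relP <- precipitation(reg) / ave(precipitation(reg), mon)
  sr <- apply(stackValues(hyd$SR), 3, mean)
  seasonal <- ave(sr, mon)
  expect_lt(cor(sr - seasonal, relP), -0.5)
})

test_that("soil moisture ends a planted drought below its climatology", {
  hits <- 0
  for (s in 1:100) {
    cfg <- scenarioConfig(seed = s, nrow = 4L, ncol = 4L, nStations = 4L,
      droughts = list(list(startYear = 2011L, startMonth = 5L,
                           months = 8L, preMultiplier = 0.3,
                           tmpOffset = 1)))
    sim <- simulateClimate(cfg)
    reg <- regionalClimate(sim$stations)
    hyd <- simulateHydrothermal(cfg, reg)
    ym <- monthIndex(hyd$SM)
    lastMonth <- max(sim$groundTruth$forcingWindows[[1]])
    sm <- apply(stackValues(hyd$SM), 3, mean)
    sameCal <- ymMonth(ym) == ymMonth(lastMonth) & ym != lastMonth
    hits <- hits + (sm[ym == lastMonth] < mean(sm[sameCal]))
  }
  expect_gte(hits, 95)
})

test_that("the full scenario recovers the planted structure end to end", {
  scn <- simulateScenario(scenarioConfig(seed = 16))
  gt <- scn$climate$groundTruth
  expect_identical(gt$sensitivityOrder, c("MDW", "SCR", "BDF", "GRA", "NDF"))
  # at least one detected event overlaps the expected window strongly
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  js <- vapply(seq_len(nrow(scn$events)), function(i)
    jacc(ymSeq(scn$events$onset[i], scn$events$termination[i]),
         gt$expectedWindow), numeric(1))
  expect_gte(max(js), 0.75)
  # karst cells respond more strongly than non-karst cells
  ks <- scn$karstSummary
  expect_lt(ks$mean[ks$stratum == "K"], ks$mean[ks$stratum == "NK"])
})
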