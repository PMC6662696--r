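noiselessConfig <- function(...) {
  scenarioConfig(nYears = 3, nLat = 2, nLon = 2, innovationSD = 0,
                 ar1 = 0, ensoCoupling = 0, latGradient = 0,
                 blocks = list(list(latIdx = 1:2, lonIdx = 1:2,
                                    trend = 0, offset = 0)),
                 ...)
}

test_that("noise-free scenario reduces to mean plus seasonal cycle", {
  cfg <- noiselessConfig()
  sim <- simulateSST(cfg)
  sst <- cubeValues(sim$sst)
  doy <- as.integer(format(timeAxis(sim$sst), "%j"))
  expected <- 28 + 1.5 * cos(2 * pi * (doy - 258) / 365.25)
  for (i in 1:2) for (j in 1:2)
    expect_equal(as.numeric(sst[i, j, ]), expected, tolerance = 1e-12)
  ## MMM = mean + amplitude, up to monthly-averaging flattening of the peak
  expect_equal(as.numeric(mmmValues(sim$mmm)),
               rep(28 + 1.5, 4), tolerance = 0.02)
})

test_that("identical configs simulate to identical outputs", {
  cfg <- scenarioConfig(nYears = 3, nLat = 3, nLon = 3, seed = 99)
  a <- simulateSST(cfg)
  b <- simulateSST(cfg)
  expect_identical(cubeValues(a$sst), cubeValues(b$sst))
  expect_identical(mmmValues(a$mmm), mmmValues(b$mmm))
  expect_identical(oniValues(a$oni), oniValues(b$oni))
  ## a different seed changes the noise
  c2 <- simulateSST(scenarioConfig(nYears = 3, nLat = 3, nLon = 3,
                                   seed = 100))
  expect_false(identical(cubeValues(a$sst), cubeValues(c2$sst)))
})

test_that("planted warming trend is recovered by OLS on annual means", {
  slopes <- vapply(1:60, function(s) {
    cfg <- scenarioConfig(nYears = 33, nLat = 1, nLon = 1,
                          ar1 = 0.7, innovationSD = 0.3,
                          ensoCoupling = 0, seed = s,
                          blocks = list(list(latIdx = 1, lonIdx = 1,
                                             trend = 0.05, offset = 0)))
    sim <- simulateSST(cfg)
    yrMean <- tapply(cubeValues(sim$sst)[1, 1, ],
                     format(timeAxis(sim$sst), "%Y"), mean)
    unname(coef(lm(yrMean ~ seq_along(yrMean)))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.05), 0.02)
})

test_that("overlapping blocks are rejected", {
  expect_error(
    scenarioConfig(nLat = 4, nLon = 4,
                   blocks = list(list(latIdx = 1:3, lonIdx = 1:4),
                                 list(latIdx = 3:4, lonIdx = 1:4))),
    "overlap")
})

test_that("plantChangepoint shifts the mean from the given year only", {
  cfg <- noiselessConfig()
  base <- simulateSST(cfg)
  shifted <- simulateSST(plantChangepoint(cfg, 1986, 1.0))
  d <- cubeValues(shifted$sst)[1, 1, ] - cubeValues(base$sst)[1, 1, ]
  yr <- as.integer(format(timeAxis(base$sst), "%Y"))
  expect_equal(max(abs(d[yr == 1985])), 0)
  expect_equal(range(d[yr >= 1986]), c(1, 1), tolerance = 1e-9)
  ## zero step simulates identically
  same <- simulateSST(plantChangepoint(cfg, 1986, 0))
  expect_identical(cubeValues(same$sst), cubeValues(base$sst))
  expect_error(plantChangepoint(cfg, 1970, 1), "span")
})

test_that("zero-noise annual max DHW matches the closed-form trace", {
  cfg <- scenarioConfig(nYears = 4, nLat = 2, nLon = 2, innovationSD = 0,
                        ar1 = 0, ensoCoupling = 0, latGradient = 0,
                        mmmBaseYears = 2,
                        blocks = list(list(latIdx = 1:2, lonIdx = 1:2,
                                           trend = 0.5, offset = 0)))
  sim <- simulateSST(cfg)
  dd <- dhw(hotspot(sim$sst, sim$mmm))
  ## closed form: evaluate the definition directly on the deterministic trace
  trace <- cubeValues(sim$sst)[1, 1, ]
  hsTrace <- pmax(trace - mmmValues(sim$mmm)[1, 1], 0)
  dhwTrace <- oracleDHW(hsTrace)
  expect_equal(as.numeric(cubeValues(dd)[1, 1, ]), dhwTrace,
               tolerance = 1e-9)
  am <- annualMaxDHW(dd)
  yrs <- format(timeAxis(dd), "%Y")
  for (k in seq_along(gridYears(am)))
    expect_equal(cubeValues(am)[1, 1, k],
                 max(dhwTrace[yrs == as.character(gridYears(am)[k])],
                     na.rm = TRUE))
})

test_that("injected ENSO coupling lag is recovered from monthly SST anomalies", {
  peaks <- vapply(1:10, function(s) {
    cfg <- scenarioConfig(nYears = 33, nLat = 1, nLon = 1,
                          ar1 = 0.5, innovationSD = 0.2,
                          ensoCoupling = 0.6, ensoLagMonths = 8L,
                          seed = s,
                          blocks = list(list(latIdx = 1, lonIdx = 1,
                                             trend = 0, offset = 0)))
    sim <- simulateSST(cfg)
    mo <- format(timeAxis(sim$sst), "%Y-%m")
    sstMonthly <- as.numeric(tapply(cubeValues(sim$sst)[1, 1, ], mo, mean))
    ## deseasonalize by removing the monthly climatology
    mIdx <- rep_len(1:12, length(sstMonthly))
    anom <- sstMonthly - ave(sstMonthly, mIdx)
    cc <- crossCorrelation(anom, oniValues(sim$oni), maxLag = 24)
    cc$lag[which.max(cc$r)]
  }, numeric(1))
  mode <- as.integer(names(sort(table(peaks), decreasing = TRUE))[1])
  expect_equal(mode, 8L)
})
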