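mkSST <- function(flat, nLat, nLon, start = as.Date("2000-01-01")) {
  nd <- ncol(flat)
  SSTCube(seq(start, by = "day", length.out = nd),
          lat = 10 + seq_len(nLat) * 0.05,
          lon = -80 + seq_len(nLon) * 0.05,
          sst = array(flat, c(nLat, nLon, nd)),
          mask = matrix(TRUE, nLat, nLon))
}

test_that("hotspot clamps at the baseline", {
  sst <- mkSST(matrix(c(29.5, 28.0, 29.0), 1, 3), 1, 1)
  mmm <- MMMGrid(latitudes(sst), longitudes(sst), matrix(29.0, 1, 1))
  hs <- hotspot(sst, mmm)
  expect_equal(as.numeric(cubeValues(hs)[1, 1, ]), c(0.5, 0, 0))
  misaligned <- MMMGrid(latitudes(sst) + 1, longitudes(sst),
                        matrix(29, 1, 1))
  expect_error(hotspot(sst, misaligned), "aligned")
})

test_that("dhw reproduces the closed-form accumulation cases", {
  ## constant 1.0 degC HotSpot for 84 days -> 12 degC-weeks on day 84
  hs <- makeHotSpotCube(matrix(1.0, 1, 84), 1, 1)
  expect_equal(cubeValues(dhw(hs))[1, 1, 84], 12)
  expect_true(all(is.na(cubeValues(dhw(hs))[1, 1, 1:83])))
  ## 0.9 degC stays below the inclusion cutoff
  hs <- makeHotSpotCube(matrix(0.9, 1, 84), 1, 1)
  expect_equal(cubeValues(dhw(hs))[1, 1, 84], 0)
  ## 7 days of 2.0 inside the window -> 2.0 degC-weeks
  v <- rep(0, 84); v[40:46] <- 2.0
  hs <- makeHotSpotCube(matrix(v, 1, 84), 1, 1)
  expect_equal(cubeValues(dhw(hs))[1, 1, 84], 2)
  ## too-short series names the required length
  expect_error(dhw(makeHotSpotCube(matrix(1, 1, 50), 1, 1)), "84")
})

test_that("rolling DHW equals brute-force re-summation on random cubes", {
  set.seed(42)
  for (rep in 1:3) {
    nLat <- 4; nLon <- 4; nd <- 400
    flat <- matrix(pmax(0, rnorm(nLat * nLon * nd, 0.8, 0.8)),
                   nLat * nLon, nd)
    flat[sample(length(flat), 200)] <- NA    # scattered missing days
    hs <- makeHotSpotCube(flat, nLat, nLon)
    got <- matrix(cubeValues(dhw(hs)), nLat * nLon, nd)
    for (px in sample(nLat * nLon, 5))
      expect_equal(got[px, ], oracleDHW(flat[px, ]), tolerance = 1e-9)
  }
})

test_that("DHW is translation-equivariant and monotone in SST", {
  set.seed(7)
  nd <- 200
  base <- rnorm(nd, 29, 1)
  sst <- mkSST(matrix(base, 1, nd), 1, 1)
  mmm <- MMMGrid(latitudes(sst), longitudes(sst), matrix(28.5, 1, 1))
  d1 <- cubeValues(dhw(hotspot(sst, mmm)))[1, 1, ]
  ## add 3 degC to both SST and MMM: DHW unchanged
  sst2 <- mkSST(matrix(base + 3, 1, nd), 1, 1)
  mmm2 <- MMMGrid(latitudes(sst), longitudes(sst), matrix(31.5, 1, 1))
  d2 <- cubeValues(dhw(hotspot(sst2, mmm2)))[1, 1, ]
  expect_equal(d1, d2, tolerance = 1e-9)
  ## raising any single day never decreases any DHW value
  for (day in sample(nd, 5)) {
    bumped <- base
    bumped[day] <- bumped[day] + 1.5
    d3 <- cubeValues(dhw(hotspot(mkSST(matrix(bumped, 1, nd), 1, 1),
                                 mmm)))[1, 1, ]
    expect_true(all(d3 - d1 >= -1e-12, na.rm = TRUE))
  }
})

test_that("windows with more than 10% missing days are reported missing", {
  v <- rep(2, 120)
  v[10:25] <- NA                      # 16 missing days
  hs <- makeHotSpotCube(matrix(v, 1, 120), 1, 1)
  got <- cubeValues(dhw(hs))[1, 1, ]
  expect_equal(got, oracleDHW(v), tolerance = 1e-9)
  expect_true(any(is.na(got[84:120])))
  expect_false(all(is.na(got[84:120])))
})

test_that("annual maximum grids have one value per pixel-year", {
  ## constant DHW all year and a single-day spike
  nd <- 365 * 2 + 366
  v <- rep(3, nd)
  julySpike <- which(format(seq(as.Date("2000-01-01"), by = "day",
                                length.out = nd), "%Y-%m-%d") == "2001-07-15")
  v[julySpike] <- 9.5
  hs <- makeHotSpotCube(matrix(v, 1, nd), 1, 1,
                        start = as.Date("2000-01-01"))
  dd <- dhw(hs)
  dd@values[] <- array(v, dim(dd@values))   # treat trace as DHW directly
  am <- annualMaxDHW(dd)
  expect_equal(gridYears(am), 2000:2002)
  expect_equal(as.numeric(cubeValues(am)[1, 1, ]), c(3, 9.5, 3))
})

test_that("a 33-year cube yields 33 annual values per pixel", {
  sim <- simulateSST(scenarioConfig(nYears = 33, nLat = 2, nLon = 2,
                                    seed = 5))
  am <- annualMaxDHW(dhw(hotspot(sim$sst, sim$mmm)))
  expect_equal(dim(cubeValues(am)), c(2, 2, 33))
  expect_equal(gridYears(am), 1985:2017)
  ## first year is flagged: the 83-day spin-up leaves >10% of days missing
  expect_true(all(am@flagged[, , 1]))
  expect_false(any(am@flagged[, , 2]))
})
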