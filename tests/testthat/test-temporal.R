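mkDHWCube <- function(flat, nLat, nLon, start = as.Date("2000-01-01")) {
  nd <- ncol(flat)
  new("DHWCube", time = seq(start, by = "day", length.out = nd),
      lat = 10 + seq_len(nLat) * 0.05, lon = -80 + seq_len(nLon) * 0.05,
      values = array(flat, c(nLat, nLon, nd)),
      mask = matrix(TRUE, nLat, nLon), varname = "dhw",
      units = "degC-weeks")
}

test_that("regional series take the cross-pixel daily median", {
  nd <- 10
  flat <- rbind(rep(0, nd), rep(4, nd), rep(10, nd), rep(1, nd))
  dd <- mkDHWCube(flat, 2, 2)
  labels <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  rs <- regionalSeries(dd, labels)
  expect_equal(rs$value[rs$region == 1], rep(4, nd))   # median {0,4,10}
  expect_equal(rs$value[rs$region == 2], rep(1, nd))   # single pixel
  ## invariant under permutation of member pixels
  perm <- rbind(flat[3, ], flat[2, ], flat[1, ], flat[4, ])
  rs2 <- regionalSeries(mkDHWCube(perm, 2, 2), labels)
  expect_equal(rs2$value, rs$value)
})

test_that("monthly means average the daily series per calendar month", {
  nd <- 90
  daily <- data.frame(region = 1L,
                      date = seq(as.Date("2000-01-01"), by = "day",
                                 length.out = nd),
                      value = rep(c(1, 2, 3), times = c(31, 29, 30)))
  mm <- monthlyMean(daily)
  expect_equal(nrow(mm), 3)
  expect_equal(mm$value, c(1, 2, 3))
})

test_that("Pettitt statistic matches the double-sum oracle exactly", {
  ## the canonical step case first
  x <- c(rep(0, 5), rep(1, 5))
  pt <- pettitt(x)
  expect_equal(pt$K, 25)
  expect_equal(pt$tau, 5L)
  set.seed(123)
  for (case in 1:25) {
    n <- sample(10:120, 1)
    x <- rnorm(n) + (runif(1) < 0.5) * (seq_len(n) > n / 2) * runif(1, 0, 2)
    if (runif(1) < 0.3) x <- round(x)       # ties exercise the sign sum
    want <- oraclePettitt(x)
    got <- pettitt(x)
    expect_equal(got$K, want$K)
    expect_equal(got$tau, want$tau)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(abs(got$U), abs(want$U))
  }
  ## constant series: no change point
  expect_equal(pettitt(rep(1, 20))$K, 0)
  expect_equal(pettitt(rep(1, 20))$p, 1)
  expect_true(is.na(pettitt(rep(1, 20))$tau))
  expect_error(pettitt(1:5), "at least 10")
})

test_that("a 12-month sinusoid lights the 12-month wavelet band", {
  t <- 1:256
  x <- 3 + 2 * sin(2 * pi * t / 12)
  wv <- waveletPower(x, logOffset = 1)
  sig <- which(wv$signif, arr.ind = TRUE)
  expect_gt(nrow(sig), 0)
  sigPeriods <- wv$periods[sig[, 1]]
  expect_true(all(sigPeriods > 8 & sigPeriods < 18))
  ## band power peaks at ~12 months in the series interior
  interior <- wv$power[, 64:192]
  expect_lt(abs(wv$periods[which.max(rowMeans(interior))] - 12), 2)
})

test_that("degenerate wavelet inputs behave", {
  expect_equal(max(waveletPower(rep(0, 128))$rawPower), 0)
  expect_error(waveletPower(rep(-2, 128), logOffset = 1), "non-positive")
  expect_error(waveletPower(rnorm(30)), "64")
})

test_that("total wavelet power tracks series variance (Parseval-style)", {
  set.seed(31)
  stats <- t(replicate(50, {
    x <- as.numeric(arima.sim(list(ar = runif(1, 0, 0.8)), 128,
                              sd = runif(1, 0.5, 3)))
    wv <- waveletPower(x, logOffset = NA)
    ## scale-corrected power is the Parseval-consistent total
    c(pow = mean(wv$power), v = var(x))
  }))
  expect_gt(cor(stats[, "pow"], stats[, "v"]), 0.95)
})

test_that("cross-wavelet of a series with itself is its power, phase zero", {
  set.seed(32)
  x <- as.numeric(arima.sim(list(ar = 0.5), 200)) + 5
  cw <- crossWavelet(x, x, logOffset = NA)
  wv <- waveletPower(x, logOffset = NA)
  expect_equal(cw$power, wv$power, tolerance = 1e-10)
  expect_equal(max(abs(cw$phase)), 0, tolerance = 1e-10)
})

test_that("a lag shows up as a consistent cross-wavelet phase angle", {
  t <- 1:256
  x <- sin(2 * pi * t / 12)
  y <- sin(2 * pi * (t - 3) / 12)          # y lags x by 3 months
  cw <- crossWavelet(x, y, logOffset = NA)
  band <- which.min(abs(cw$periods - 12))
  ph <- cw$phase[band, 64:192]
  expect_equal(mean(ph), 2 * pi * 3 / 12, tolerance = 0.1)
  expect_lt(sd(ph), 0.05)
  expect_error(crossWavelet(x, y[1:100]), "lengths differ")
})

test_that("cross-correlation conventions: self lag 0, known lead recovered", {
  set.seed(33)
  x <- rnorm(300)
  cc <- crossCorrelation(x, x, maxLag = 10)
  expect_equal(cc$r[cc$lag == 0], 1)
  expect_equal(cc$lag, -10:10)
  ## dhw(t) = oni(t - 8) + noise: peak at +8 (ONI leads)
  oni <- as.numeric(arima.sim(list(ar = 0.8), 400))
  dhwS <- c(rep(0, 8), oni[1:392]) + rnorm(400, sd = 0.1)
  cc8 <- crossCorrelation(dhwS, oni, maxLag = 20)
  expect_equal(cc8$lag[which.max(cc8$r)], 8)
  expect_true(cc8$significant[cc8$lag == 8])
  expect_error(crossCorrelation(rnorm(50), rnorm(50), maxLag = 38),
               "overlap")
})

test_that("independent noise rarely crosses the significance bounds", {
  set.seed(34)
  anyHit <- replicate(40, {
    cc <- crossCorrelation(rnorm(250), rnorm(250), maxLag = 10)
    mean(cc$significant)
  })
  expect_lt(mean(anyHit), 0.10)   # per-lag 5% nominal
})
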