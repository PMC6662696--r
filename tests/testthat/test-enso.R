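mkONI <- function(valsByYear, startYear = 2000) {
  n <- length(valsByYear)
  ONISeries(seq(as.Date(sprintf("%d-01-01", startYear)), by = "month",
                length.out = n), valsByYear)
}

test_that("phase classification follows the month-count rule", {
  ## 7 months at +0.8 dominate
  oni <- mkONI(c(rep(0.8, 7), rep(0, 5)))
  expect_equal(as.character(classifyEnso(oni)$phase), "ElNino")
  ## all neutral
  expect_equal(as.character(classifyEnso(mkONI(rep(0, 12)))$phase),
               "Neutral")
  ## 6 warm vs 6 cold with equal magnitude: full tie falls back to Neutral
  tie <- mkONI(c(rep(0.2, 6), rep(-0.2, 6)))
  expect_equal(as.character(classifyEnso(tie)$phase), "Neutral")
  ## unequal magnitudes break the tie
  warmTie <- mkONI(c(rep(0.5, 6), rep(-0.2, 6)))
  expect_equal(as.character(classifyEnso(warmTie)$phase), "ElNino")
  ## four qualifying months are not enough
  few <- mkONI(c(rep(0.9, 4), rep(0, 8)))
  expect_equal(as.character(classifyEnso(few)$phase), "Neutral")
  expect_error(classifyEnso(mkONI(rep(0, 15))), "partial")
})

test_that("phase classification equals the counting oracle on random series", {
  set.seed(41)
  for (case in 1:300) {
    v <- round(as.numeric(arima.sim(list(ar = 0.85), 24, sd = 0.3)), 2)
    oni <- mkONI(v)
    got <- as.character(classifyEnso(oni)$phase)
    want <- c(oracleEnsoPhase(v[1:12]), oracleEnsoPhase(v[13:24]))
    expect_equal(got, want)
  }
})

test_that("annual stress is the hottest monthly mean of each year", {
  months <- seq(as.Date("2000-01-01"), by = "month", length.out = 24)
  v <- rep(0, 24); v[7] <- 6.2; v[13:24] <- 2
  as1 <- annualStress(data.frame(month = months, value = v))
  expect_equal(as1$value, c(6.2, 2))
  expect_equal(as1$year, c(2000, 2001))
  ## partial years are dropped with a warning
  expect_warning(
    as2 <- annualStress(data.frame(month = months[1:20], value = v[1:20])),
    "coverage")
  expect_equal(as2$year, 2000)
  ## a 33-year series gives 33 values
  m33 <- seq(as.Date("1985-01-01"), by = "month", length.out = 396)
  expect_equal(nrow(annualStress(data.frame(month = m33,
                                            value = runif(396)))), 33)
})

phasesFor <- function(years, phase = NULL) {
  set.seed(7)
  ph <- if (is.null(phase))
    sample(c("Neutral", "ElNino", "LaNina"), length(years), replace = TRUE,
           prob = c(0.5, 0.25, 0.25)) else rep(phase, length(years))
  data.frame(year = years,
             phase = factor(ph, levels = c("Neutral", "ElNino", "LaNina")))
}

test_that("Gamma GLM deviance table has the printed df pattern", {
  set.seed(42)
  years <- 1985:2017                      # n = 33
  ph <- phasesFor(years)
  y <- rgamma(33, shape = 8,
              rate = 8 / exp(0.5 + 0.03 * (years - 1985) +
                             0.2 * (ph$phase == "ElNino")))
  res <- fitStressGLM(data.frame(year = years, value = y), ph)
  tab <- res$devianceTable
  expect_equal(tab$term, c("Null", "Years", "ENSO"))
  expect_equal(tab$df[2:3], c(1, 2))
  expect_equal(tab$dfr[2:3], c(30, 28))
  ## residual deviance is non-increasing down the table
  expect_true(all(diff(tab$residDeviance) <= 1e-12))
  expect_gt(res$explainedDeviance, 0)
  expect_true(is.finite(res$aicc))
})

test_that("identical responses give a null year effect", {
  years <- 1985:2017
  res <- fitStressGLM(data.frame(year = years, value = rep(2, 33)),
                      phasesFor(years))
  expect_equal(unname(res$coef["year"]), 0, tolerance = 1e-8)
  expect_lt(res$devianceTable$F[2], 1e-6)
})

test_that("zero responses are epsilon-shifted with a warning", {
  years <- 1985:2017
  v <- c(rep(0, 3), runif(30, 0.5, 4))
  expect_warning(res <- fitStressGLM(data.frame(year = years, value = v),
                                     phasesFor(years)), "shifted")
  expect_true(is.finite(res$aicc))
})

test_that("GLS-AR1 recovers slope and autocorrelation structure", {
  set.seed(43)
  years <- 1985:2017
  ph <- phasesFor(years)
  slopes <- replicate(60, {
    e <- as.numeric(arima.sim(list(ar = 0.5), 33, sd = 0.4))
    y <- 2 + 0.05 * (years - 1985) + e
    unname(fitStressGLS(data.frame(year = years, value = y), ph)$coef["year"])
  })
  expect_lt(abs(mean(slopes) - 0.05), 0.01)
  ## independent errors: estimated AR1 parameter near zero on average
  phis <- replicate(40, {
    y <- 2 + rnorm(33, sd = 0.5)
    fitStressGLS(data.frame(year = years, value = y), ph)$phi
  })
  expect_lt(abs(mean(phis)), 0.25)
  ## constant series: zero slope
  resC <- fitStressGLS(data.frame(year = years, value = rep(2, 33)), ph)
  expect_equal(unname(resC$coef["year"]), 0, tolerance = 1e-8)
})

test_that("model comparison selects the lower AICc and reports ties", {
  a <- list(kind = "GLM-Gamma-log", aicc = 100, residLag1 = 0.1)
  b <- list(kind = "GLS-AR1", aicc = 105, residLag1 = 0.05)
  cmp <- compareStressModels(a, b)
  expect_equal(cmp$selected, "GLM-Gamma-log")
  expect_equal(cmp$deltaAICc, 5)
  tie <- compareStressModels(a, list(kind = "GLS-AR1", aicc = 100,
                                     residLag1 = 0))
  expect_true(is.na(tie$selected))
})

test_that("Gamma-generated data mostly prefers the Gamma GLM", {
  set.seed(44)
  years <- 1985:2017
  ph <- phasesFor(years)
  wins <- replicate(40, {
    y <- rgamma(33, shape = 4,
                rate = 4 / exp(0.3 + 0.04 * (years - 1985)))
    glmR <- fitStressGLM(data.frame(year = years, value = y), ph)
    glsR <- fitStressGLS(data.frame(year = years, value = y), ph)
    identical(compareStressModels(glmR, glsR)$selected, "GLM-Gamma-log")
  })
  expect_gt(mean(wins), 0.5)
})

test_that("AICc equals AIC plus the closed-form small-sample correction", {
  set.seed(45)
  years <- 1985:2017
  ph <- phasesFor(years)
  y <- rgamma(33, shape = 6, rate = 6 / exp(0.5 + 0.02 * (years - 1985)))
  res <- fitStressGLM(data.frame(year = years, value = y), ph)
  k <- attr(logLik(res$fit), "df")
  n <- 33
  expect_equal(res$aicc, AIC(res$fit) + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-12)
})
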