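#' Per-pixel heat-stress exposure summary
#'
#' Computes the event-count exposure metrics from per-pixel annual maximum
#' DHW series: the series maximum, the number of years at or above the
#' bleaching-risk threshold (default 4 degC-weeks) and the mortality-risk
#' threshold (default 8 degC-weeks), and the calendar year of the maximum
#' (ties broken to the earliest year). Trend metrics are filled in by
#' [trendGrid()] when `trend = TRUE`.
#'
#' @param annualMax an [AnnualMaxGrid] with at least 2 years.
#' @param bleachThr,mortThr event thresholds in degC-weeks (defaults 4, 8).
#' @param trend if TRUE (default), also fit the per-pixel GLS-AR1 trend via
#'   [trendGrid()] and store the significance-zeroed slopes.
#' @param alpha significance level for trend zeroing (default 0.05).
#' @return an [ExposureSummary].
#' @export
exposureSummary <- function(annualMax, bleachThr = 4, mortThr = 8,
                            trend = TRUE, alpha = 0.05) {
  stopifnot(is(annualMax, "AnnualMaxGrid"))
  if (length(annualMax@years) < 2)
    stop("need at least 2 years of annual maxima")
  d <- dim(annualMax@values)
  npix <- d[1] * d[2]
  flat <- matrix(annualMax@values, nrow = npix)  # pixel x year
  allNA <- rowSums(!is.na(flat)) == 0
  mx <- suppressWarnings(apply(flat, 1, max, na.rm = TRUE))
  mx[allNA] <- NA_real_
  nb <- rowSums(flat >= bleachThr, na.rm = TRUE)
  nm <- rowSums(flat >= mortThr, na.rm = TRUE)
  ym <- apply(flat, 1, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))  # earliest tie
  yearOfMax <- annualMax@years[ym]
  nb[allNA] <- NA_integer_
  nm[allNA] <- NA_integer_

  toM <- function(v, mode = "numeric") {
    m <- matrix(v, d[1], d[2])
    m[!annualMax@mask] <- NA
    m
  }
  obj <- new("ExposureSummary",
             lat = annualMax@lat, lon = annualMax@lon,
             maxDhw = toM(mx),
             nBleaching = toM(as.integer(nb)),
             nMortality = toM(as.integer(nm)),
             yearOfMax = toM(as.integer(yearOfMax)),
             trendSlope = toM(NA_real_),
             trendP = toM(NA_real_),
             mask = annualMax@mask,
             bleachThr = bleachThr, mortThr = mortThr)
  if (trend) {
    tg <- trendGrid(annualMax, alpha = alpha)
    obj@trendSlope <- tg$slope
    obj@trendP <- tg$p
  }
  obj
}

#' GLS trend with AR1 errors for an annual series
#'
#' Fits `value ~ time` by generalized least squares with an AR1 error
#' covariance, the AR1 parameter estimated from the data (restricted maximum
#' likelihood by default; see Details), and returns the slope with its
#' two-sided p-value for the null of zero trend. No seasonal terms enter:
#' the input is annual.
#'
#' Details: REML is used for inference because its small-sample bias
#' correction of the AR1/variance estimates keeps the test's type-I error
#' near nominal at series lengths around 30, where plain ML is measurably
#' liberal. A constant series returns slope 0 with p = 1; if the AR1 fit
#' fails to converge the ordinary least-squares fit (AR1 = 0) is used.
#'
#' @param series numeric vector of annual values.
#' @param years optional numeric time covariate (default `1:n`).
#' @param method `"REML"` (default) or `"ML"`.
#' @return named vector `c(slope =, p =)`, slope in units per year.
#' @export
glsAr1Trend <- function(series, years = seq_along(series),
                        method = c("REML", "ML")) {
  method <- match.arg(method)
  ok <- is.finite(series)
  if (sum(ok) < 10)
    stop("need at least 10 finite annual values")
  y <- series[ok]
  t <- years[ok]
  if (stats::sd(y) == 0)
    return(c(slope = 0, p = 1))
  df <- data.frame(y = y, t = t)
  ## an exactly linear series has no residual variance to model
  ols <- stats::lm(y ~ t, data = df)
  if (suppressWarnings(summary(ols))$sigma < 1e-10)
    return(c(slope = unname(stats::coef(ols)[2]), p = 0))
  fit <- tryCatch(
    nlme::gls(y ~ t, data = df,
              correlation = nlme::corAR1(form = ~t), method = method),
    error = function(e) NULL)
  if (is.null(fit)) {
    sm <- summary(ols)$coefficients
    return(c(slope = unname(sm["t", "Estimate"]),
             p = unname(sm["t", "Pr(>|t|)"])))
  }
  tt <- summary(fit)$tTable
  c(slope = unname(tt["t", "Value"]), p = unname(tt["t", "p-value"]))
}

#' Per-pixel trend grid with significance zeroing
#'
#' Applies [glsAr1Trend()] to every masked pixel of an annual-maximum grid
#' and zeroes slopes whose p-value exceeds `alpha`, so the returned slope
#' grid shows only trends distinguishable from zero at the chosen
#' confidence. Pixels whose fit fails or that lack enough years are missing.
#'
#' @param annualMax an [AnnualMaxGrid] with >= 10 years.
#' @param alpha significance level (default 0.05, i.e. 95% confidence).
#' @param method estimation method passed to [glsAr1Trend()].
#' @return `list(slope, p)`: matrices \code{[nLat, nLon]}; slope is zeroed
#'   wherever `p > alpha`.
#' @export
trendGrid <- function(annualMax, alpha = 0.05, method = "REML") {
  stopifnot(is(annualMax, "AnnualMaxGrid"))
  if (length(annualMax@years) < 10)
    stop("need at least 10 years for trend estimation")
  d <- dim(annualMax@values)
  npix <- d[1] * d[2]
  flat <- matrix(annualMax@values, nrow = npix)
  slope <- rep(NA_real_, npix)
  pval <- rep(NA_real_, npix)
  for (i in which(as.vector(annualMax@mask))) {
    v <- flat[i, ]
    if (sum(is.finite(v)) < 10) next
    res <- tryCatch(glsAr1Trend(v, annualMax@years, method = method),
                    error = function(e) c(slope = NA_real_, p = NA_real_))
    slope[i] <- res["slope"]
    pval[i] <- res["p"]
  }
  slope[!is.na(pval) & pval > alpha] <- 0
  list(slope = matrix(slope, d[1], d[2]),
       p = matrix(pval, d[1], d[2]))
}
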