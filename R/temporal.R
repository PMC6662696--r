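#' Regional daily median DHW series
#'
#' Summarizes the DHW cube at regional scale: for each region and day, the
#' median DHW across the region's member pixels.
#'
#' @param dhwCube a [DHWCube].
#' @param labeling a [RegionLabeling] aligned with the cube (or an integer
#'   label matrix).
#' @return data.frame with columns `region, date, value`; regions with no
#'   pixels are absent.
#' @export
regionalSeries <- function(dhwCube, labeling) {
  stopifnot(is(dhwCube, "DHWCube"))
  labels <- if (is(labeling, "RegionLabeling")) labeling@labels else labeling
  if (!all(dim(labels) == dim(dhwCube@values)[1:2]))
    stop("labels do not align with the cube grid")
  d <- dim(dhwCube@values)
  flat <- matrix(dhwCube@values, nrow = d[1] * d[2])
  labs <- as.vector(labels)
  regions <- sort(unique(labs[!is.na(labs)]))
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    rows <- which(!is.na(labs) & labs == regions[i])
    med <- apply(flat[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    out[[i]] <- data.frame(region = regions[i], date = dhwCube@time,
                           value = med)
  }
  do.call(rbind, out)
}

#' Monthly means of regional daily series
#'
#' Low-pass filters daily regional series to the monthly scale (the
#' resolution of the ONI) by averaging within each calendar month.
#'
#' @param daily data.frame `region, date, value` from [regionalSeries()].
#' @return data.frame `region, month, value` with `month` the first day of
#'   each month.
#' @export
monthlyMean <- function(daily) {
  stopifnot(all(c("region", "date", "value") %in% names(daily)))
  mo <- as.Date(format(as.Date(daily$date), "%Y-%m-01"))
  agg <- stats::aggregate(daily$value,
                          by = list(region = daily$region, month = mo),
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "value"
  agg$value[is.nan(agg$value)] <- NA_real_
  agg[order(agg$region, agg$month), ]
}

#' Pettitt change-point test
#'
#' Rank-based nonparametric test for a single change point:
#' `U_t = sum_{i<=t} sum_{j>t} sign(x_j - x_i)`, `K = max|U_t|`, with the
#' change located at the last index of the first segment
#' (`tau = argmax|U_t|`) and approximate significance
#' `p = 2 exp(-6 K^2 / (n^3 + n^2))`.
#'
#' @param series numeric vector (monthly values; n >= 10). NAs are dropped
#'   with their time positions retained in `tau` indexing.
#' @return list `K` (statistic), `tau` (index of change; NA for a constant
#'   series), `p`, and `U` (the statistic path).
#' @export
pettitt <- function(series) {
  ok <- which(is.finite(series))
  x <- series[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 values")
  if (stats::sd(x) == 0)
    return(list(K = 0, tau = NA_integer_, p = 1,
                U = rep(0, n - 1)))
  ## V_t = sum_j sign(x_t - x_j); U_t = U_{t-1} + V_t (exact double sum)
  V <- vapply(seq_len(n), function(t) sum(sign(x[t] - x)), numeric(1))
  U <- cumsum(V)[-n]
  K <- max(abs(U))
  tau <- which.max(abs(U))
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  list(K = K, tau = ok[tau], p = p, U = U)
}

## ---- Morlet continuous wavelet machinery ----------------------------------

## CWT of x at dyadic scales (omega0 = 6), zero-padded to the next power of
## two; returns the complex transform, scales, equivalent Fourier periods
## and the cone of influence (maximum trustworthy period per time step).
.morletCWT <- function(x, dt = 1, dj = 1 / 12, s0 = 2 * dt, jTot = NULL) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, npad - n))
  omega0 <- 6
  k <- seq_len(npad %/% 2)
  wk <- 2 * pi * k / (npad * dt)
  wk <- c(0, wk, -rev(wk[seq_len((npad - 1) %/% 2)]))
  fx <- stats::fft(xp)
  if (is.null(jTot))
    jTot <- floor(log2(n * dt / s0) / dj)
  scales <- s0 * 2^(dj * (0:jTot))
  W <- matrix(complex(real = 0, imaginary = 0), length(scales), n)
  norm0 <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- norm0 * sqrt(2 * pi * s / dt) * exp(-(s * wk - omega0)^2 / 2) *
      (wk > 0)
    W[j, ] <- stats::fft(fx * psi, inverse = TRUE)[seq_len(n)] / npad
  }
  fourierFactor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- fourierFactor * scales
  edge <- pmin(seq_len(n) - 1, n - seq_len(n))
  coi <- fourierFactor / sqrt(2) * dt * pmax(edge, 1e-8)
  list(W = W, scales = scales, periods = periods, coi = coi, dt = dt,
       n = n)
}

## Theoretical lag-1 autoregressive (red-noise) spectrum at each period.
.redNoiseSpectrum <- function(periods, dt, alpha) {
  freq <- dt / periods
  (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * freq))
}

#' Morlet wavelet power spectrum with red-noise significance
#'
#' Continuous Morlet wavelet transform (omega0 = 6) of
#' `log(series + logOffset)`, with pointwise 95% significance against a
#' lag-1 autoregressive background spectrum (chi-square with 2 df) and the
#' standard e-folding cone of influence. The log transform tames the skewed
#' DHW distribution; the offset accommodates the zeros of quiet months.
#'
#' @param series numeric monthly series (n >= 64).
#' @param dt sampling interval in months (default 1).
#' @param logOffset offset added before the log (default 1); use
#'   `logOffset = NA` to skip the transform.
#' @param sigLevel significance level (default 0.95).
#' @return list with `periods` (months), `times`, `power` (bias-corrected,
#'   |W|^2 / scale), `rawPower` (|W|^2), `signif` (logical matrix), `coi`
#'   (maximum trustworthy period per time), `inCoi` (logical matrix), and
#'   the lag-1 coefficient used for the background.
#' @export
waveletPower <- function(series, dt = 1, logOffset = 1, sigLevel = 0.95) {
  if (length(series) < 64) stop("need at least 64 months")
  x <- series
  if (!is.na(logOffset)) {
    if (any(x + logOffset <= 0, na.rm = TRUE))
      stop("non-positive values after adding logOffset")
    x <- log(x + logOffset)
  }
  if (anyNA(x)) stop("series contains missing values")
  cw <- .morletCWT(x, dt = dt)
  rawPower <- Mod(cw$W)^2
  power <- sweep(rawPower, 1, cw$scales, "/")
  varx <- stats::var(x)
  if (varx == 0) {
    signif <- matrix(FALSE, nrow(rawPower), ncol(rawPower))
    alpha <- 0
  } else {
    alpha <- max(0, min(0.99, stats::acf(x, plot = FALSE,
                                         lag.max = 1)$acf[2]))
    Pk <- .redNoiseSpectrum(cw$periods, dt, alpha)
    thresh <- varx * Pk * stats::qchisq(sigLevel, df = 2) / 2
    signif <- sweep(rawPower, 1, thresh, ">")
  }
  inCoi <- outer(cw$periods, cw$coi, "<=")
  signif <- signif & inCoi
  list(periods = cw$periods, times = seq_len(cw$n) * dt, power = power,
       rawPower = rawPower, signif = signif, coi = cw$coi, inCoi = inCoi,
       lag1 = alpha)
}

#' Bias-corrected cross-wavelet between a DHW series and the ONI
#'
#' Cross-wavelet transform `Wxy = Wx conj(Wy)` of the (log-transformed)
#' regional DHW series against the ONI, on a common monthly axis. Power is
#' bias-corrected by dividing by scale; phase angles give the lead/lag
#' relationship within each significant band. Significance at `sigLevel`
#' tests the null that the series share no common variation, via the
#' chi-square distribution of the cross power under independent lag-1
#' autoregressive backgrounds; interpretation is restricted to the cone of
#' influence.
#'
#' @param dhwSeries numeric monthly DHW series.
#' @param oni an [ONISeries] or numeric vector of equal length.
#' @param dt months per step (default 1).
#' @param logOffset log offset applied to the DHW series (default 1; the
#'   ONI, being an anomaly, is not transformed).
#' @param sigLevel significance level (default 0.95).
#' @return list with `periods, times, power` (bias-corrected |Wxy|/scale),
#'   `phase` (radians), `signif`, `coi`, `inCoi`.
#' @export
crossWavelet <- function(dhwSeries, oni, dt = 1, logOffset = 1,
                         sigLevel = 0.95) {
  y <- if (is(oni, "ONISeries")) oni@oni else oni
  if (length(dhwSeries) != length(y))
    stop("series lengths differ (", length(dhwSeries), " vs ",
         length(y), ")")
  x <- dhwSeries
  if (!is.na(logOffset)) {
    if (any(x + logOffset <= 0, na.rm = TRUE))
      stop("non-positive values after adding logOffset")
    x <- log(x + logOffset)
  }
  if (anyNA(x) || anyNA(y)) stop("series contain missing values")
  cx <- .morletCWT(x, dt = dt)
  cy <- .morletCWT(y, dt = dt)
  Wxy <- cx$W * Conj(cy$W)
  crossPow <- Mod(Wxy)
  power <- sweep(crossPow, 1, cx$scales, "/")
  phase <- Arg(Wxy)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    signif <- matrix(FALSE, nrow(crossPow), ncol(crossPow))
  } else {
    ax <- max(0, min(0.99, stats::acf(x, plot = FALSE,
                                      lag.max = 1)$acf[2]))
    ay <- max(0, min(0.99, stats::acf(y, plot = FALSE,
                                      lag.max = 1)$acf[2]))
    Px <- .redNoiseSpectrum(cx$periods, dt, ax)
    Py <- .redNoiseSpectrum(cy$periods, dt, ay)
    ## Z_2(95%) = 3.999 for the modulus of a complex cross spectrum
    zv <- if (abs(sigLevel - 0.95) < 1e-9) 3.999
          else stats::qchisq(sigLevel, df = 2)
    thresh <- sx * sy * sqrt(Px * Py) * zv / 2
    signif <- sweep(crossPow, 1, thresh, ">")
  }
  inCoi <- outer(cx$periods, pmin(cx$coi, cy$coi), "<=")
  signif <- signif & inCoi
  list(periods = cx$periods, times = seq_len(cx$n) * dt, power = power,
       phase = phase, signif = signif, coi = cx$coi, inCoi = inCoi)
}

#' Lagged cross-correlation between DHW and the ONI
#'
#' Pearson correlation at monthly lags `-maxLag..maxLag`, with the
#' convention that a positive lag means the ONI leads the DHW series.
#' Per-lag 95% significance bounds are `+/- 1.96 / sqrt(n_overlap)`; no
#' autocorrelation adjustment is applied (a documented limitation shared
#' with common implementations).
#'
#' @param dhwSeries numeric monthly DHW series.
#' @param oni an [ONISeries] or numeric vector on the same monthly axis.
#' @param maxLag maximum lag in months (default 38, giving at least 10
#'   cycles over a 33-year record).
#' @param confLevel confidence for the bounds (default 0.95).
#' @return data.frame `lag, r, n, bound, significant`.
#' @export
crossCorrelation <- function(dhwSeries, oni, maxLag = 38L,
                             confLevel = 0.95) {
  y <- if (is(oni, "ONISeries")) oni@oni else oni
  n <- length(dhwSeries)
  if (length(y) != n)
    stop("series lengths differ")
  maxLag <- as.integer(maxLag)
  if (n < 5 * maxLag)
    stop("overlap too short: need at least ", 5 * maxLag, " months")
  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  lags <- seq.int(-maxLag, maxLag)
  res <- lapply(lags, function(L) {
    if (L >= 0) {           # ONI leads DHW by L months
      d <- dhwSeries[(1 + L):n]; o <- y[1:(n - L)]
    } else {
      d <- dhwSeries[1:(n + L)]; o <- y[(1 - L):n]
    }
    nn <- length(d)
    r <- if (stats::sd(d) == 0 || stats::sd(o) == 0) NA_real_
         else stats::cor(d, o)
    data.frame(lag = L, r = r, n = nn, bound = z / sqrt(nn))
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$r) & abs(out$r) > out$bound
  out
}
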