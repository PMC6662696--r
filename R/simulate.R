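#' ScenarioConfig: synthetic SST scenario description
#'
#' Describes a synthetic study scenario: a regular pixel grid, a daily SST
#' model (mean field with latitudinal gradient, single-sinusoid seasonal
#' cycle peaking in late boreal summer, per-block linear warming trends and
#' offsets, AR1 daily noise), a trapezoidal-event ENSO forcing series that
#' warms SST with a fixed lag, an optional planted regime-shift step, and the
#' reef-point layout. Identical configs simulate to identical outputs (the
#' seed is part of the config).
#'
#' @slot nYears,startYear simulated span (calendar years).
#' @slot nLat,nLon,lat0,lon0,cellDeg grid shape and pixel-center origin /
#'   spacing (decimal degrees).
#' @slot meanSST mean SST at `lat0` (degC).
#' @slot latGradient degC per degree latitude (negative = cooler northwards).
#' @slot seasonalAmp,peakDoy seasonal sinusoid amplitude (degC) and day of
#'   year of the seasonal maximum.
#' @slot ar1,innovationSD daily AR1 noise coefficient (in `[0,1)`) and
#'   innovation standard deviation (degC).
#' @slot ensoAmp,ensoCoupling,ensoLagMonths ENSO event amplitude scale
#'   (degC of ONI), SST response per degC of ONI, and the coupling lag
#'   (months; ONI leads SST).
#' @slot ensoEvents data.frame event calendar (columns `startMonth, rise,
#'   plateau, decay, amplitude`); empty = default quasi-periodic calendar.
#' @slot blocks list of pixel blocks, each
#'   `list(latIdx =, lonIdx =, trend =, offset =)` with trend in degC/year.
#' @slot stepYear,stepC planted upward mean shift (calendar year it starts,
#'   size in degC); `stepC = 0` disables it.
#' @slot mmmBaseYears number of leading years used as the climatology base
#'   period (capped at `nYears`).
#' @slot seed integer RNG seed.
#'
#' @aliases ScenarioConfig
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(
    nYears = "integer", startYear = "integer",
    nLat = "integer", nLon = "integer",
    lat0 = "numeric", lon0 = "numeric", cellDeg = "numeric",
    meanSST = "numeric", latGradient = "numeric",
    seasonalAmp = "numeric", peakDoy = "numeric",
    ar1 = "numeric", innovationSD = "numeric",
    ensoAmp = "numeric", ensoCoupling = "numeric",
    ensoLagMonths = "integer", ensoEvents = "data.frame",
    blocks = "list",
    stepYear = "integer", stepC = "numeric",
    mmmBaseYears = "integer",
    seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- NULL
  if (object@nYears < 3L) msg <- c(msg, "nYears must be >= 3")
  if (object@ar1 < 0 || object@ar1 >= 1)
    msg <- c(msg, "ar1 must lie in [0, 1)")
  if (object@innovationSD < 0) msg <- c(msg, "innovationSD must be >= 0")
  seen <- matrix(FALSE, object@nLat, object@nLon)
  for (b in object@blocks) {
    if (!all(c("latIdx", "lonIdx") %in% names(b)))
      msg <- c(msg, "each block needs latIdx and lonIdx")
    else {
      if (any(b$latIdx < 1 | b$latIdx > object@nLat) ||
          any(b$lonIdx < 1 | b$lonIdx > object@nLon))
        msg <- c(msg, "block indices outside the grid")
      else {
        cells <- as.matrix(expand.grid(b$latIdx, b$lonIdx))
        if (any(seen[cells]))
          msg <- c(msg, "config error: blocks overlap")
        seen[cells] <- TRUE
      }
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Build a synthetic scenario configuration
#'
#' Defaults describe a small Caribbean-like study: a 12 x 12 grid of 0.05
#' degree pixels, 33 years of daily SST with a 1.5 degC seasonal cycle
#' peaking in mid-September, a weak north-south gradient, AR1(0.7) daily
#' noise of 0.3 degC innovation SD, two contiguous exposure blocks (a warmer,
#' faster-warming southern block and a cooler, slowly warming northern
#' block), and ENSO forcing that leads SST by 8 months at 0.4 degC per degC
#' of ONI.
#'
#' @param nYears,startYear span; defaults 33 years from 1985.
#' @param nLat,nLon,lat0,lon0,cellDeg grid; defaults 12 x 12 at 0.05 deg
#'   from (12N, 82W).
#' @param meanSST,latGradient,seasonalAmp,peakDoy SST climatology parameters.
#' @param ar1,innovationSD daily noise model.
#' @param ensoAmp,ensoCoupling,ensoLagMonths,ensoEvents ENSO forcing;
#'   `ensoEvents = NULL` uses a default quasi-periodic alternating calendar.
#' @param blocks list of exposure blocks; `NULL` = default two-block split.
#' @param stepYear,stepC planted regime shift (disabled by default).
#' @param mmmBaseYears climatology base period length (default 28 years,
#'   mirroring a 1985-2012 base in a 1985-start series).
#' @param seed RNG seed.
#' @return a [ScenarioConfig].
#' @export
scenarioConfig <- function(nYears = 33L, startYear = 1985L,
                           nLat = 12L, nLon = 12L,
                           lat0 = 12, lon0 = -82, cellDeg = 0.05,
                           meanSST = 28, latGradient = -0.1,
                           seasonalAmp = 1.5, peakDoy = 258,
                           ar1 = 0.7, innovationSD = 0.3,
                           ensoAmp = 1.8, ensoCoupling = 0.4,
                           ensoLagMonths = 8L, ensoEvents = NULL,
                           blocks = NULL,
                           stepYear = NA_integer_, stepC = 0,
                           mmmBaseYears = 28L,
                           seed = 1L) {
  if (is.null(blocks)) {
    half <- nLat %/% 2L
    blocks <- list(
      list(latIdx = seq_len(half), lonIdx = seq_len(nLon),
           trend = 0.04, offset = 0.6),
      list(latIdx = seq.int(half + 1L, nLat), lonIdx = seq_len(nLon),
           trend = 0.015, offset = 0)
    )
  }
  if (is.null(ensoEvents))
    ensoEvents <- .defaultEnsoCalendar(nYears, ensoAmp)
  new("ScenarioConfig",
      nYears = as.integer(nYears), startYear = as.integer(startYear),
      nLat = as.integer(nLat), nLon = as.integer(nLon),
      lat0 = lat0, lon0 = lon0, cellDeg = cellDeg,
      meanSST = meanSST, latGradient = latGradient,
      seasonalAmp = seasonalAmp, peakDoy = peakDoy,
      ar1 = ar1, innovationSD = innovationSD,
      ensoAmp = ensoAmp, ensoCoupling = ensoCoupling,
      ensoLagMonths = as.integer(ensoLagMonths), ensoEvents = ensoEvents,
      blocks = blocks,
      stepYear = as.integer(stepYear), stepC = stepC,
      mmmBaseYears = as.integer(mmmBaseYears),
      seed = as.integer(seed))
}

## Quasi-periodic alternating warm/cold trapezoidal events, one every ~4
## years, amplitudes varied deterministically so no two events are equal.
.defaultEnsoCalendar <- function(nYears, ensoAmp) {
  starts <- seq(14, nYears * 12 - 18, by = 50)
  n <- length(starts)
  amp <- ensoAmp * rep_len(c(1, -0.7, 0.6, -0.5, 1.4, -0.8), n)
  data.frame(startMonth = starts,
             rise = rep_len(c(4L, 3L, 5L), n),
             plateau = rep_len(c(5L, 4L, 6L), n),
             decay = rep_len(c(5L, 6L, 4L), n),
             amplitude = amp)
}

## Piecewise-trapezoidal monthly forcing from an event calendar; event
## timing is exact, which recovery tests rely on.
.trapezoidSeries <- function(nMonths, events) {
  x <- numeric(nMonths)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    ramp <- c(seq(0, 1, length.out = e$rise + 1L)[-1L],
              rep(1, e$plateau),
              seq(1, 0, length.out = e$decay + 1L)[-1L])
    idx <- e$startMonth + seq_along(ramp) - 1L
    keep <- idx >= 1L & idx <= nMonths
    x[idx[keep]] <- x[idx[keep]] + e$amplitude * ramp[keep]
  }
  x
}

#' Simulate a synthetic SST scenario
#'
#' Generates the four linked inputs of the exposure pipeline from a
#' [ScenarioConfig]: a daily [SSTCube], the matching [MMMGrid] (warmest
#' monthly climatological mean over the base period), the synthetic
#' [ONISeries], and a [ReefPointSet] covering the grid. Daily SST is
#'
#' mean + gradient x lat + seasonal sinusoid + block trend x t +
#' block offset + coupling x ONI(t - lag) + step + AR1 noise.
#'
#' @param config a [ScenarioConfig].
#' @return `list(sst, mmm, oni, reefs)`.
#' @export
simulateSST <- function(config) {
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  withr::with_seed(config@seed, .simulateSSTImpl(config))
}

.simulateSSTImpl <- function(config) {
  nYears <- config@nYears
  firstDay <- as.Date(sprintf("%d-01-01", config@startYear))
  lastDay <- as.Date(sprintf("%d-12-31", config@startYear + nYears - 1L))
  time <- seq(firstDay, lastDay, by = "day")
  nd <- length(time)
  lat <- config@lat0 + (seq_len(config@nLat) - 1L) * config@cellDeg
  lon <- config@lon0 + (seq_len(config@nLon) - 1L) * config@cellDeg
  npix <- config@nLat * config@nLon

  nMonths <- nYears * 12L
  oniMonths <- seq(firstDay, by = "month", length.out = nMonths)
  oniVals <- .trapezoidSeries(nMonths, config@ensoEvents)
  oni <- ONISeries(oniMonths, oniVals)

  ## ONI forcing on SST, lagged: month index of each day minus lag
  mIdx <- (as.integer(format(time, "%Y")) - config@startYear) * 12L +
    as.integer(format(time, "%m"))
  lagIdx <- mIdx - config@ensoLagMonths
  forcing <- ifelse(lagIdx >= 1L & lagIdx <= nMonths,
                    config@ensoCoupling * oniVals[pmax(lagIdx, 1L)], 0)

  doy <- as.integer(format(time, "%j"))
  seasonal <- config@seasonalAmp *
    cos(2 * pi * (doy - config@peakDoy) / 365.25)
  tYears <- as.numeric(time - firstDay) / 365.25

  step <- if (!is.na(config@stepYear) && config@stepC != 0) {
    if (config@stepYear < config@startYear ||
        config@stepYear > config@startYear + nYears - 1L)
      stop("stepYear outside the simulated span")
    config@stepC * (time >= as.Date(sprintf("%d-01-01", config@stepYear)))
  } else 0

  trendPix <- numeric(npix)
  offsetPix <- numeric(npix)
  for (b in config@blocks) {
    cells <- as.matrix(expand.grid(b$latIdx, b$lonIdx))
    flat <- (cells[, 2] - 1L) * config@nLat + cells[, 1]
    trendPix[flat] <- if (is.null(b$trend)) 0 else b$trend
    offsetPix[flat] <- if (is.null(b$offset)) 0 else b$offset
  }
  basePix <- config@meanSST +
    config@latGradient * (rep(lat, times = config@nLon) - config@lat0) +
    offsetPix

  ## pixel x time deterministic field
  sstFlat <- outer(basePix, rep(1, nd)) +
    outer(trendPix, tYears) +
    matrix(seasonal + forcing + step, npix, nd, byrow = TRUE)

  if (config@innovationSD > 0) {
    innov <- matrix(stats::rnorm(npix * nd, sd = config@innovationSD),
                    npix, nd)
    if (config@ar1 > 0) {
      noise <- t(apply(innov, 1, function(e)
        as.numeric(stats::filter(e, config@ar1, method = "recursive"))))
    } else noise <- innov
    sstFlat <- sstFlat + noise
  }

  arr <- array(sstFlat, c(config@nLat, config@nLon, nd))
  sst <- SSTCube(time, lat, lon, arr,
                 mask = matrix(TRUE, config@nLat, config@nLon))
  baseYears <- seq(config@startYear,
                   length.out = min(config@mmmBaseYears, nYears))
  mmm <- computeMMM(sst, baseYears = baseYears)

  ## reef points at every other pixel center so the 20-km buffer spans all
  ## blocks
  ri <- seq(1L, config@nLat, by = 2L)
  rj <- seq(1L, config@nLon, by = 2L)
  pts <- expand.grid(lat = lat[ri], lon = lon[rj])
  reefs <- ReefPointSet(pts$lon, pts$lat)

  list(sst = sst, mmm = mmm, oni = oni, reefs = reefs)
}

#' Plant a regime-shift change point in a scenario
#'
#' Returns a config whose simulated SST mean shifts upward by `stepC`
#' degrees from 1 January of `year` onward; used to test change-point
#' recovery.
#'
#' @param config a [ScenarioConfig].
#' @param year calendar year at which the shift starts (must lie in the
#'   simulated span).
#' @param stepC step size in degC.
#' @return the modified [ScenarioConfig].
#' @export
plantChangepoint <- function(config, year, stepC) {
  stopifnot(is(config, "ScenarioConfig"))
  year <- as.integer(year)
  if (year < config@startYear ||
      year > config@startYear + config@nYears - 1L)
    stop("year outside the simulated span (",
         config@startYear, "..", config@startYear + config@nYears - 1L, ")")
  config@stepYear <- year
  config@stepC <- stepC
  validObject(config)
  config
}
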