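#' Coral bleaching HotSpots
#'
#' Daily positive SST anomaly above the Maximum Monthly Mean baseline:
#' `hs = max(sst - mmm, 0)` per pixel and day. Anomalies at or below the
#' baseline are zero; the HotSpot itself is reported unthresholded (the
#' 1 degC inclusion cutoff applies only to DHW accumulation).
#'
#' @param sst an [SSTCube].
#' @param mmm an [MMMGrid] on the same grid.
#' @return a [HotSpotCube].
#' @export
hotspot <- function(sst, mmm) {
  stopifnot(is(sst, "SSTCube"), is(mmm, "MMMGrid"))
  if (!isTRUE(all.equal(sst@lat, mmm@lat)) ||
      !isTRUE(all.equal(sst@lon, mmm@lon)))
    stop("SST cube and MMM grid are not aligned")
  nd <- dim(sst@values)[3]
  hs <- sst@values - array(rep(mmm@mmm, nd), dim = dim(sst@values))
  hs[hs < 0] <- 0
  new("HotSpotCube", time = sst@time, lat = sst@lat, lon = sst@lon,
      values = hs, mask = sst@mask, varname = "hs", units = "degC")
}

#' Degree Heating Weeks
#'
#' Accumulates HotSpots of at least 1 degC over a trailing window of
#' `windowDays` calendar days (inclusive of the current day) and divides by
#' 7 to express the result in degC-weeks:
#' `dhw(t) = (1/7) * sum over the window of hs_i * [hs_i >= 1]`, computed
#' daily. The first `windowDays - 1` days are reported missing rather than
#' accumulated over a partial window; windows with more than 10% missing
#' days are also reported missing (available days are summed otherwise —
#' no interpolation is applied).
#'
#' @param hs a [HotSpotCube].
#' @param windowDays accumulation window (default 84 days = 12 weeks).
#' @param hsCutoff inclusion cutoff in degC (default 1).
#' @param maxMissingFrac maximum tolerated fraction of missing days in a
#'   window (default 0.1).
#' @return a [DHWCube].
#' @export
dhw <- function(hs, windowDays = 84L, hsCutoff = 1, maxMissingFrac = 0.1) {
  stopifnot(is(hs, "HotSpotCube"))
  windowDays <- as.integer(windowDays)
  nd <- dim(hs@values)[3]
  if (nd < windowDays)
    stop("series too short: ", nd, " days < required window of ",
         windowDays, " days")
  d <- dim(hs@values)
  npix <- d[1] * d[2]
  flat <- matrix(hs@values, nrow = npix)          # pixel x time
  contrib <- flat
  contrib[is.na(contrib) | contrib < hsCutoff] <- 0
  miss <- is.na(flat) + 0

  ## trailing-window sums via cumulative sums along time
  csum <- t(apply(contrib, 1, cumsum))
  cmiss <- t(apply(miss, 1, cumsum))
  out <- matrix(NA_real_, npix, nd)
  ## trailing difference: sum over days (t - windowDays + 1) .. t
  idx <- seq.int(windowDays, nd)
  prev <- idx - windowDays
  wsum <- csum[, idx, drop = FALSE]
  nonzero <- prev >= 1L
  if (any(nonzero))
    wsum[, nonzero] <- wsum[, nonzero] -
      csum[, prev[nonzero], drop = FALSE]
  wmiss <- cmiss[, idx, drop = FALSE]
  if (any(nonzero))
    wmiss[, nonzero] <- wmiss[, nonzero] -
      cmiss[, prev[nonzero], drop = FALSE]
  vals <- wsum / 7
  vals[wmiss / windowDays > maxMissingFrac] <- NA_real_
  out[, idx] <- vals

  new("DHWCube", time = hs@time, lat = hs@lat, lon = hs@lon,
      values = array(out, d), mask = hs@mask,
      varname = "dhw", units = "degC-weeks")
}

#' Annual maximum DHW per pixel
#'
#' The main exposure indicator: for each pixel and calendar year, the
#' maximum daily DHW within that year. Pixel-years with more than
#' `maxMissingFrac` of days missing are flagged (the maximum over available
#' days is still reported); all-missing pixel-years are NA.
#'
#' @param dhwCube a [DHWCube].
#' @param maxMissingFrac flagging threshold (default 0.1).
#' @return an [AnnualMaxGrid].
#' @export
annualMaxDHW <- function(dhwCube, maxMissingFrac = 0.1) {
  stopifnot(is(dhwCube, "DHWCube"))
  yr <- as.integer(format(dhwCube@time, "%Y"))
  years <- sort(unique(yr))
  d <- dim(dhwCube@values)
  npix <- d[1] * d[2]
  flat <- matrix(dhwCube@values, nrow = npix)
  vals <- array(NA_real_, c(d[1], d[2], length(years)))
  flags <- array(FALSE, c(d[1], d[2], length(years)))
  for (i in seq_along(years)) {
    sel <- yr == years[i]
    sub <- flat[, sel, drop = FALSE]
    mx <- apply(sub, 1, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    fr <- rowMeans(is.na(sub))
    vals[, , i] <- matrix(mx, d[1], d[2])
    flags[, , i] <- matrix(fr > maxMissingFrac, d[1], d[2])
  }
  off <- !dhwCube@mask
  if (any(off))
    for (i in seq_along(years)) {
      v <- vals[, , i]; v[off] <- NA_real_; vals[, , i] <- v
    }
  new("AnnualMaxGrid", years = years, lat = dhwCube@lat, lon = dhwCube@lon,
      values = vals, mask = dhwCube@mask, flagged = flags)
}
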