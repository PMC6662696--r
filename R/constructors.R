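#' Construct an SSTCube
#'
#' @param time Date vector (daily, strictly increasing).
#' @param lat,lon pixel-center coordinates, strictly increasing (decimal
#'   degrees, EPSG:4326).
#' @param sst numeric array \code{[nLat, nLon, nTime]} in degrees C.
#' @param mask logical \code{[nLat, nLon]} analysis mask; defaults to all
#'   pixels with at least one finite value.
#' @return an [SSTCube].
#' @export
SSTCube <- function(time, lat, lon, sst, mask = NULL) {
  if (is.null(mask))
    mask <- apply(is.finite(sst), c(1, 2), any)
  new("SSTCube", time = as.Date(time), lat = as.numeric(lat),
      lon = as.numeric(lon), values = sst, mask = mask,
      varname = "sst", units = "degC")
}

#' Construct an MMMGrid
#'
#' @param lat,lon pixel-center coordinates.
#' @param mmm numeric matrix \code{[nLat, nLon]}, degrees C.
#' @return an [MMMGrid].
#' @export
MMMGrid <- function(lat, lon, mmm) {
  new("MMMGrid", lat = as.numeric(lat), lon = as.numeric(lon), mmm = mmm)
}

#' Construct a ReefPointSet
#'
#' @param lon,lat point coordinates in decimal degrees.
#' @param region optional character labels per point.
#' @return a [ReefPointSet].
#' @export
ReefPointSet <- function(lon, lat, region = character()) {
  new("ReefPointSet",
      coords = cbind(lon = as.numeric(lon), lat = as.numeric(lat)),
      region = as.character(region))
}

#' Construct an ONISeries
#'
#' @param month Date vector; coerced to the first day of each month.
#' @param oni numeric monthly anomalies (degC).
#' @return an [ONISeries].
#' @export
ONISeries <- function(month, oni) {
  month <- as.Date(format(as.Date(month), "%Y-%m-01"))
  new("ONISeries", month = month, oni = as.numeric(oni))
}

#' Compute a Maximum Monthly Mean climatology from an SST cube
#'
#' For each pixel, averages daily SST by calendar month over the base years,
#' then takes the warmest of the 12 monthly climatological means. This is the
#' standard bleaching baseline construction.
#'
#' @param sst an [SSTCube].
#' @param baseYears integer vector of calendar years to use as the
#'   climatology base period; default all years in the cube.
#' @return an [MMMGrid].
#' @export
computeMMM <- function(sst, baseYears = NULL) {
  stopifnot(is(sst, "SSTCube"))
  yr <- as.integer(format(sst@time, "%Y"))
  mo <- as.integer(format(sst@time, "%m"))
  if (is.null(baseYears)) baseYears <- unique(yr)
  inBase <- yr %in% baseYears
  if (!any(inBase))
    stop("no days of the cube fall inside 'baseYears'")
  d <- dim(sst@values)
  npix <- d[1] * d[2]
  flat <- matrix(sst@values, nrow = npix)   # pixel x time
  monthly <- matrix(NA_real_, npix, 12)
  for (m in 1:12) {
    sel <- inBase & mo == m
    if (any(sel))
      monthly[, m] <- rowMeans(flat[, sel, drop = FALSE], na.rm = TRUE)
  }
  mmm <- apply(monthly, 1, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  mmm <- matrix(mmm, d[1], d[2])
  mmm[!sst@mask] <- NA_real_
  MMMGrid(sst@lat, sst@lon, mmm)
}
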