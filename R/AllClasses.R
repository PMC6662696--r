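#' @import methods
NULL

## Central containers are (lat, lon, time) cubes on a regular pixel-center
## grid (EPSG:4326). values is an array [nLat, nLon, nTime]; mask is an
## [nLat, nLon] logical matrix, TRUE where the pixel is analyzed.

#' GeoCube: gridded daily field on a regular lat/lon grid
#'
#' Base container for daily gridded fields on a regular pixel-center
#' latitude/longitude grid. Holds a \code{[nLat, nLon, nTime]} numeric array,
#' the coordinate vectors, a per-pixel analysis mask and the variable
#' name/units. Subclasses add field-specific validity: [SSTCube] (sea-surface
#' temperature, degrees C), [HotSpotCube] (daily positive anomalies above the
#' bleaching baseline) and [DHWCube] (Degree Heating Weeks, degC-weeks).
#'
#' @slot time Date vector, strictly increasing, daily.
#' @slot lat,lon numeric vectors of pixel-center coordinates (decimal
#'   degrees), strictly increasing.
#' @slot values numeric array \code{[nLat, nLon, nTime]}.
#' @slot mask logical matrix \code{[nLat, nLon]}; TRUE = analyzed pixel.
#' @slot varname,units single strings describing the field.
#'
#' @aliases GeoCube
#' @exportClass GeoCube
setClass("GeoCube",
  representation(
    time = "Date",
    lat = "numeric",
    lon = "numeric",
    values = "array",
    mask = "matrix",
    varname = "character",
    units = "character"
  )
)

.validGeoCube <- function(object) {
  msg <- NULL
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "'values' must be a 3-d array [lat, lon, time]")
  else {
    if (d[1] != length(object@lat) || d[2] != length(object@lon) ||
        d[3] != length(object@time))
      msg <- c(msg, "dim(values) must match (length(lat), length(lon), length(time))")
    if (!all(dim(object@mask) == d[1:2]))
      msg <- c(msg, "dim(mask) must match (length(lat), length(lon))")
  }
  if (anyNA(object@time))
    msg <- c(msg, "'time' contains NA")
  if (length(object@time) > 1) {
    dt <- diff(as.integer(object@time))
    if (any(dt <= 0))
      msg <- c(msg, "'time' must be strictly increasing with no duplicates")
    else if (any(dt > 31))
      msg <- c(msg, "'time' has gaps larger than 31 days")
  }
  if (is.unsorted(object@lat, strictly = TRUE))
    msg <- c(msg, "'lat' must be strictly increasing")
  if (is.unsorted(object@lon, strictly = TRUE))
    msg <- c(msg, "'lon' must be strictly increasing")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (is.null(msg)) TRUE else msg
}
setValidity("GeoCube", .validGeoCube)

#' @rdname GeoCube-class
#' @aliases SSTCube
#' @exportClass SSTCube
setClass("SSTCube", contains = "GeoCube")

setValidity("SSTCube", function(object) {
  v <- object@values[rep(object@mask, dim(object@values)[3])]
  fin <- v[is.finite(v)]
  msg <- NULL
  if (length(fin) && (min(fin) < -5 || max(fin) > 45))
    msg <- c(msg, "masked SST outside plausible range [-5, 45] degC")
  if (length(v) && mean(is.finite(v)) < 0.99)
    msg <- c(msg, "more than 1% of masked SST values are missing")
  if (is.null(msg)) TRUE else msg
})

#' @rdname GeoCube-class
#' @aliases HotSpotCube
#' @exportClass HotSpotCube
setClass("HotSpotCube", contains = "GeoCube")

setValidity("HotSpotCube", function(object) {
  v <- object@values
  if (any(v[is.finite(v)] < 0)) "HotSpot values must be >= 0" else TRUE
})

#' @rdname GeoCube-class
#' @aliases DHWCube
#' @exportClass DHWCube
setClass("DHWCube", contains = "GeoCube")

setValidity("DHWCube", function(object) {
  v <- object@values
  if (any(v[is.finite(v)] < 0)) "DHW values must be >= 0" else TRUE
})

#' MMMGrid: Maximum Monthly Mean climatology
#'
#' Per-pixel warmest monthly climatological mean SST (degrees C), the
#' bleaching baseline against which daily HotSpots are measured.
#'
#' @slot lat,lon pixel-center coordinates as in [GeoCube].
#' @slot mmm numeric matrix \code{[nLat, nLon]}, degrees C; NA on unmasked
#'   pixels.
#'
#' @aliases MMMGrid
#' @exportClass MMMGrid
setClass("MMMGrid",
  representation(lat = "numeric", lon = "numeric", mmm = "matrix")
)

setValidity("MMMGrid", function(object) {
  msg <- NULL
  if (!all(dim(object@mmm) == c(length(object@lat), length(object@lon))))
    msg <- c(msg, "dim(mmm) must match (length(lat), length(lon))")
  fin <- object@mmm[is.finite(object@mmm)]
  if (length(fin) && (min(fin) < -5 || max(fin) > 45))
    msg <- c(msg, "MMM outside plausible SST range")
  if (is.null(msg)) TRUE else msg
})

#' ReefPointSet: reef point locations
#'
#' Reef locations as (lon, lat) points in decimal degrees, with an optional
#' region label per point.
#'
#' @slot coords two-column numeric matrix (lon, lat).
#' @slot region character vector of per-point labels (may be empty).
#'
#' @aliases ReefPointSet
#' @exportClass ReefPointSet
setClass("ReefPointSet",
  representation(coords = "matrix", region = "character")
)

setValidity("ReefPointSet", function(object) {
  msg <- NULL
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "'coords' must have two columns (lon, lat)")
  if (anyNA(object@coords))
    msg <- c(msg, "reef coordinates contain NA")
  else {
    if (any(abs(object@coords[, 2]) > 90))
      msg <- c(msg, "latitude outside [-90, 90]")
    if (any(abs(object@coords[, 1]) > 360))
      msg <- c(msg, "longitude outside [-360, 360]")
  }
  if (length(object@region) &&
      length(object@region) != nrow(object@coords))
    msg <- c(msg, "'region' must be empty or one label per point")
  if (is.null(msg)) TRUE else msg
})

#' ONISeries: monthly Oceanic Nino Index
#'
#' Monthly ONI anomalies (degrees C) on an exact monthly time axis. Each
#' entry is dated to the first day of its month.
#'
#' @slot month Date vector (first of month), strictly increasing, gap-free.
#' @slot oni numeric anomalies, degrees C.
#'
#' @aliases ONISeries
#' @exportClass ONISeries
setClass("ONISeries",
  representation(month = "Date", oni = "numeric")
)

.monthIndex <- function(d) {
  as.integer(format(d, "%Y")) * 12L + as.integer(format(d, "%m"))
}

setValidity("ONISeries", function(object) {
  msg <- NULL
  if (length(object@month) != length(object@oni))
    msg <- c(msg, "'month' and 'oni' lengths differ")
  if (length(object@month) > 1) {
    dm <- diff(.monthIndex(object@month))
    if (any(dm != 1L))
      msg <- c(msg, "monthly spacing must be exact (no gaps, no duplicates)")
  }
  if (anyNA(object@oni) || any(!is.finite(object@oni)))
    msg <- c(msg, "ONI values must be finite")
  else if (any(abs(object@oni) >= 6))
    msg <- c(msg, "implausible ONI magnitude (|oni| >= 6)")
  if (is.null(msg)) TRUE else msg
})

#' AnnualMaxGrid: per-pixel annual maximum DHW
#'
#' Annual maxima of daily DHW per pixel, the main exposure indicator and the
#' clustering feature space for heat-stress regionalization.
#'
#' @slot years integer calendar years.
#' @slot lat,lon pixel-center coordinates.
#' @slot values numeric array \code{[nLat, nLon, nYears]}, degC-weeks.
#' @slot mask logical analysis mask.
#' @slot flagged logical array \code{[nLat, nLon, nYears]}; TRUE where the
#'   pixel-year had more than 10% of days missing.
#'
#' @aliases AnnualMaxGrid
#' @exportClass AnnualMaxGrid
setClass("AnnualMaxGrid",
  representation(
    years = "integer",
    lat = "numeric",
    lon = "numeric",
    values = "array",
    mask = "matrix",
    flagged = "array"
  )
)

setValidity("AnnualMaxGrid", function(object) {
  msg <- NULL
  d <- dim(object@values)
  if (length(d) != 3L ||
      d[1] != length(object@lat) || d[2] != length(object@lon) ||
      d[3] != length(object@years))
    msg <- c(msg, "dim(values) must be (nLat, nLon, nYears)")
  if (!identical(dim(object@flagged), dim(object@values)))
    msg <- c(msg, "dim(flagged) must match dim(values)")
  v <- object@values
  if (any(v[is.finite(v)] < 0))
    msg <- c(msg, "annual maximum DHW must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' ExposureSummary: per-pixel heat-stress exposure indicators
#'
#' The five per-pixel exposure metrics: maximum DHW over the whole series,
#' counts of bleaching-risk (annual max >= 4 degC-weeks) and mortality-risk
#' (>= 8 degC-weeks) years, the calendar year of the maximum, and the
#' (significance-zeroed) annual trend with its p-value.
#'
#' @slot lat,lon pixel-center coordinates.
#' @slot maxDhw,trendSlope,trendP numeric matrices \code{[nLat, nLon]}.
#' @slot nBleaching,nMortality,yearOfMax integer matrices.
#' @slot mask logical analysis mask.
#' @slot bleachThr,mortThr thresholds used (degC-weeks).
#'
#' @aliases ExposureSummary
#' @exportClass ExposureSummary
setClass("ExposureSummary",
  representation(
    lat = "numeric", lon = "numeric",
    maxDhw = "matrix",
    nBleaching = "matrix",
    nMortality = "matrix",
    yearOfMax = "matrix",
    trendSlope = "matrix",
    trendP = "matrix",
    mask = "matrix",
    bleachThr = "numeric",
    mortThr = "numeric"
  )
)

setValidity("ExposureSummary", function(object) {
  msg <- NULL
  ok <- object@mask & is.finite(object@nBleaching) &
    is.finite(object@nMortality)
  if (any(object@nMortality[ok] > object@nBleaching[ok]))
    msg <- c(msg, "mortality-event count exceeds bleaching-event count")
  if (is.null(msg)) TRUE else msg
})

#' RegionLabeling: heat-stress region assignment
#'
#' K-means heat-stress regionalization of the annual-maximum-DHW feature
#' space, with clustering diagnostics. Labels are renumbered so that region 1
#' has the highest mean exposure (descending mean of cluster centers).
#'
#' @slot labels integer matrix \code{[nLat, nLon]}; NA off-mask.
#' @slot k number of regions.
#' @slot centers matrix \code{[k, nYears]} of cluster centers (degC-weeks).
#' @slot inertiaCurve total within-cluster sum of squares for k = 1..kMax
#'   (empty if only a single k was fit).
#' @slot pcaCoords per-pixel scores on the first two principal components of
#'   the feature matrix (rows named by pixel index).
#' @slot years feature years.
#'
#' @aliases RegionLabeling
#' @exportClass RegionLabeling
setClass("RegionLabeling",
  representation(
    labels = "matrix",
    k = "integer",
    centers = "matrix",
    inertiaCurve = "numeric",
    pcaCoords = "matrix",
    years = "integer"
  )
)

setValidity("RegionLabeling", function(object) {
  msg <- NULL
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (any(lab < 1L) || any(lab > object@k)))
    msg <- c(msg, "labels must lie in 1..k")
  if (nrow(object@centers) != object@k)
    msg <- c(msg, "centers must have k rows")
  if (length(object@inertiaCurve) > 1 &&
      any(diff(object@inertiaCurve) > 1e-8 * max(object@inertiaCurve[1], 1)))
    msg <- c(msg, "inertia curve must be non-increasing in k")
  if (is.null(msg)) TRUE else msg
})
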