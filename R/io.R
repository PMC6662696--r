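## Plain-text I/O contract.
##
## Cubes  : long-format CSV with columns date, lat, lon, <var>; one row per
##          masked pixel-day. <var> is sst, hs or dhw and selects the class.
## Grids  : TSV matrix; header "lat" then the longitudes, one row per
##          latitude. NA written for unmasked pixels.
## ONI    : CSV with columns year, month, oni.
## Reefs  : CSV with columns lon, lat and optional region.
## All coordinates are pixel centers in decimal degrees, EPSG:4326.

#' Read a gridded daily cube from long-format CSV
#'
#' Reads a cube written by [writeGeoCube()] (columns `date, lat, lon` and one
#' of `sst`, `hs`, `dhw`). Values stored in Kelvin are converted to degrees C
#' when `units = "auto"` (detected by magnitude) or `units = "K"`.
#'
#' @param path CSV file.
#' @param bbox optional `c(latMin, latMax, lonMin, lonMax)` crop.
#' @param units `"auto"`, `"C"` or `"K"` (temperature cubes only).
#' @return an [SSTCube], [HotSpotCube] or [DHWCube] according to the value
#'   column.
#' @export
readGeoCube <- function(path, bbox = NULL, units = c("auto", "C", "K")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  varname <- setdiff(names(df), c("date", "lat", "lon"))
  if (!all(c("date", "lat", "lon") %in% names(df)) || length(varname) != 1L)
    stop("format error: expected columns date, lat, lon and one value column")
  if (!varname %in% c("sst", "hs", "dhw"))
    stop("format error: unknown value column '", varname, "'")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("format error: unparseable dates")
  if (!is.null(bbox)) {
    stopifnot(length(bbox) == 4)
    df <- df[df$lat >= bbox[1] & df$lat <= bbox[2] &
             df$lon >= bbox[3] & df$lon <= bbox[4], , drop = FALSE]
    if (!nrow(df)) stop("bbox excludes every pixel in the file")
  }
  val <- df[[varname]]
  if (varname == "sst" && units != "C") {
    med <- stats::median(val, na.rm = TRUE)
    if (units == "K" || (units == "auto" && isTRUE(med > 150)))
      val <- val - 273.15
  }
  time <- sort(unique(df$date))
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  iT <- match(df$date, time)
  iLa <- match(df$lat, lat)
  iLo <- match(df$lon, lon)
  idx <- cbind(iLa, iLo, iT)
  if (anyDuplicated(idx))
    stop("validation error: duplicated (date, lat, lon) entries")
  arr <- array(NA_real_, c(length(lat), length(lon), length(time)))
  arr[idx] <- val
  mask <- matrix(FALSE, length(lat), length(lon))
  mask[unique(cbind(iLa, iLo))] <- TRUE
  cls <- c(sst = "SSTCube", hs = "HotSpotCube", dhw = "DHWCube")[[varname]]
  un <- if (varname == "dhw") "degC-weeks" else "degC"
  new(cls, time = time, lat = lat, lon = lon, values = arr, mask = mask,
      varname = varname, units = un)
}

#' @rdname readGeoCube
#' @export
readSSTCube <- function(path, bbox = NULL, units = c("auto", "C", "K")) {
  cube <- readGeoCube(path, bbox = bbox, units = units)
  if (!is(cube, "SSTCube"))
    stop("file does not contain an SST cube (value column is not 'sst')")
  cube
}

#' Write a gridded daily cube to long-format CSV
#'
#' Only masked pixels are written; the mask is recovered on read from the
#' pixels present. Values round-trip to better than 1e-6 degC.
#'
#' @param cube a [GeoCube].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeGeoCube <- function(cube, path) {
  stopifnot(is(cube, "GeoCube"))
  d <- dim(cube@values)
  pix <- which(cube@mask, arr.ind = TRUE)
  if (!nrow(pix)) stop("cube has an empty mask; nothing to write")
  iLa <- rep(pix[, 1], times = d[3])
  iLo <- rep(pix[, 2], times = d[3])
  iT <- rep(seq_len(d[3]), each = nrow(pix))
  df <- data.frame(
    date = cube@time[iT],
    lat = cube@lat[iLa],
    lon = cube@lon[iLo],
    value = cube@values[cbind(iLa, iLo, iT)]
  )
  names(df)[4] <- cube@varname
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a per-pixel indicator grid (TSV matrix)
#'
#' The grid is stored as a TSV matrix with a `lat` column and one column per
#' longitude; unmasked pixels are NA. Round-trips exactly to read precision.
#'
#' @param grid numeric matrix \code{[nLat, nLon]}.
#' @param lat,lon pixel-center coordinates matching `grid`.
#' @param path file path.
#' @return `writeIndicatorGrid` returns `path` invisibly;
#'   `readIndicatorGrid` returns `list(lat, lon, values)`.
#' @export
writeIndicatorGrid <- function(grid, lat, lon, path) {
  if (!is.matrix(grid) || nrow(grid) != length(lat) ||
      ncol(grid) != length(lon))
    stop("shape mismatch: grid must be length(lat) x length(lon)")
  if (all(is.na(grid)))
    warning("writing an all-NA indicator grid")
  df <- data.frame(lat = lat, as.data.frame(grid), check.names = FALSE)
  names(df) <- c("lat", format(lon, digits = 12, scientific = FALSE,
                               trim = TRUE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIndicatorGrid
#' @export
readIndicatorGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "lat") stop("format error: first column must be 'lat'")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  lat <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  list(lat = lat, lon = as.numeric(hdr[-1]), values = vals)
}

#' Read / write a monthly ONI series (CSV)
#'
#' CSV with columns `year, month, oni`. Monthly coverage must be complete;
#' missing or duplicated months are reported.
#'
#' @param path CSV file.
#' @return an [ONISeries].
#' @export
readONI <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("year", "month", "oni") %in% names(df)))
    stop("format error: expected columns year, month, oni")
  ym <- df$year * 12L + df$month
  o <- order(ym)
  df <- df[o, ]
  ym <- ym[o]
  if (anyDuplicated(ym)) {
    d <- df[duplicated(ym), c("year", "month")]
    stop("duplicated months: ",
         paste(sprintf("%d-%02d", d$year, d$month), collapse = ", "))
  }
  gaps <- which(diff(ym) != 1L)
  if (length(gaps)) {
    miss <- unlist(lapply(gaps, function(i) seq(ym[i] + 1L, ym[i + 1] - 1L)))
    stop("missing months: ",
         paste(sprintf("%d-%02d", (miss - 1L) %/% 12L, (miss - 1L) %% 12L + 1L),
               collapse = ", "))
  }
  ONISeries(as.Date(sprintf("%d-%02d-01", df$year, df$month)), df$oni)
}

#' @rdname readONI
#' @param oni an [ONISeries] to write.
#' @export
writeONI <- function(oni, path) {
  stopifnot(is(oni, "ONISeries"))
  df <- data.frame(year = as.integer(format(oni@month, "%Y")),
                   month = as.integer(format(oni@month, "%m")),
                   oni = oni@oni)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write reef point locations (CSV)
#'
#' CSV with columns `lon, lat` and optional `region`.
#'
#' @param path CSV file.
#' @return a [ReefPointSet].
#' @export
readReefPoints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("format error: expected columns lon, lat")
  ReefPointSet(df$lon, df$lat,
               region = if ("region" %in% names(df))
                 as.character(df$region) else character())
}

#' @rdname readReefPoints
#' @param reefs a [ReefPointSet] to write.
#' @export
writeReefPoints <- function(reefs, path) {
  stopifnot(is(reefs, "ReefPointSet"))
  df <- data.frame(lon = reefs@coords[, 1], lat = reefs@coords[, 2])
  if (length(reefs@region)) df$region <- reefs@region
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## great-circle distances on a spherical Earth, R = 6371 km
.EARTH_RADIUS_M <- 6371000

#' Restrict a cube's analysis mask to reef-adjacent pixels
#'
#' Masks exactly those pixels whose center lies within `bufferKm`
#' great-circle kilometres (haversine, spherical Earth R = 6371 km) of at
#' least one reef point. The pixel whose cell contains a reef point is always
#' masked, so a zero buffer keeps exactly the reef-containing pixels.
#'
#' @param cube a [GeoCube].
#' @param reefs a [ReefPointSet]; must be non-empty.
#' @param bufferKm buffer distance in km (default 20, the reef-adjacency
#'   scale used throughout the exposure analysis).
#' @return the cube with its mask replaced (intersected with the existing
#'   mask).
#' @export
maskFromReefs <- function(cube, reefs, bufferKm = 20) {
  stopifnot(is(cube, "GeoCube"), is(reefs, "ReefPointSet"))
  if (!nrow(reefs@coords)) stop("empty reef point set")
  lat <- cube@lat
  lon <- cube@lon
  centers <- cbind(lon = rep(lon, each = length(lat)),
                   lat = rep(lat, times = length(lon)))
  halfLat <- if (length(lat) > 1) stats::median(diff(lat)) / 2 else Inf
  halfLon <- if (length(lon) > 1) stats::median(diff(lon)) / 2 else Inf
  near <- matrix(FALSE, length(lat), length(lon))
  for (i in seq_len(nrow(reefs@coords))) {
    p <- reefs@coords[i, ]
    dm <- geosphere::distHaversine(p, centers, r = .EARTH_RADIUS_M)
    hit <- dm <= bufferKm * 1000
    contain <- abs(centers[, 2] - p[2]) <= halfLat &
      abs(centers[, 1] - p[1]) <= halfLon
    near <- near | matrix(hit | contain, length(lat), length(lon))
  }
  newMask <- cube@mask & near
  if (!any(newMask))
    warning("no pixel lies within ", bufferKm, " km of a reef point")
  cube@mask <- newMask
  validObject(cube)
  cube
}
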