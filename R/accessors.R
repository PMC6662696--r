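#' Accessors for gridded containers
#'
#' Extract the coordinate axes, time axis, value array and analysis mask of
#' the gridded containers without touching slots directly.
#'
#' @param x a [GeoCube], [MMMGrid], [AnnualMaxGrid], [ExposureSummary] or
#'   [RegionLabeling] object (see individual generics for which apply).
#' @return `cubeValues` the numeric array; `cubeMask` the logical pixel mask;
#'   `timeAxis` the Date vector; `latitudes`/`longitudes` the coordinate
#'   vectors; `gridYears` the integer years of an annual grid or labeling;
#'   `regionLabels` the integer label matrix; `nRegions` the region count.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))
#' @rdname accessors
#' @export
setGeneric("cubeMask", function(x) standardGeneric("cubeMask"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("latitudes", function(x) standardGeneric("latitudes"))
#' @rdname accessors
#' @export
setGeneric("longitudes", function(x) standardGeneric("longitudes"))
#' @rdname accessors
#' @export
setGeneric("gridYears", function(x) standardGeneric("gridYears"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
setMethod("cubeValues", "GeoCube", function(x) x@values)
#' @rdname accessors
setMethod("cubeValues", "AnnualMaxGrid", function(x) x@values)
#' @rdname accessors
setMethod("cubeMask", "GeoCube", function(x) x@mask)
#' @rdname accessors
setMethod("cubeMask", "AnnualMaxGrid", function(x) x@mask)
#' @rdname accessors
setMethod("cubeMask", "ExposureSummary", function(x) x@mask)
#' @rdname accessors
setMethod("timeAxis", "GeoCube", function(x) x@time)
#' @rdname accessors
setMethod("timeAxis", "ONISeries", function(x) x@month)
#' @rdname accessors
setMethod("latitudes", "GeoCube", function(x) x@lat)
#' @rdname accessors
setMethod("latitudes", "MMMGrid", function(x) x@lat)
#' @rdname accessors
setMethod("latitudes", "AnnualMaxGrid", function(x) x@lat)
#' @rdname accessors
setMethod("latitudes", "ExposureSummary", function(x) x@lat)
#' @rdname accessors
setMethod("longitudes", "GeoCube", function(x) x@lon)
#' @rdname accessors
setMethod("longitudes", "MMMGrid", function(x) x@lon)
#' @rdname accessors
setMethod("longitudes", "AnnualMaxGrid", function(x) x@lon)
#' @rdname accessors
setMethod("longitudes", "ExposureSummary", function(x) x@lon)
#' @rdname accessors
setMethod("gridYears", "AnnualMaxGrid", function(x) x@years)
#' @rdname accessors
setMethod("gridYears", "RegionLabeling", function(x) x@years)
#' @rdname accessors
setMethod("regionLabels", "RegionLabeling", function(x) x@labels)
#' @rdname accessors
setMethod("nRegions", "RegionLabeling", function(x) x@k)

#' MMM values of an MMMGrid
#' @param x an [MMMGrid].
#' @return numeric matrix of the warmest monthly climatological means (degC).
#' @export
mmmValues <- function(x) {
  stopifnot(is(x, "MMMGrid"))
  x@mmm
}

#' Coordinates of a ReefPointSet
#' @param x a [ReefPointSet].
#' @return two-column (lon, lat) matrix.
#' @export
reefCoords <- function(x) {
  stopifnot(is(x, "ReefPointSet"))
  x@coords
}

#' ONI anomaly values
#' @param x an [ONISeries].
#' @return numeric vector of monthly anomalies (degC).
#' @export
oniValues <- function(x) {
  stopifnot(is(x, "ONISeries"))
  x@oni
}

#' Exposure metric grids from an ExposureSummary
#'
#' @param x an [ExposureSummary].
#' @param metric one of `"maxDhw"`, `"nBleaching"`, `"nMortality"`,
#'   `"yearOfMax"`, `"trendSlope"`, `"trendP"`.
#' @return the requested per-pixel matrix.
#' @export
exposureMetric <- function(x, metric = c("maxDhw", "nBleaching",
                                         "nMortality", "yearOfMax",
                                         "trendSlope", "trendP")) {
  stopifnot(is(x, "ExposureSummary"))
  metric <- match.arg(metric)
  slot(x, metric)
}

setMethod("show", "GeoCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %s [%s]\n", class(object), object@varname, object@units))
  cat(sprintf("  grid : %d lat x %d lon (%.3f..%.3f, %.3f..%.3f)\n",
              d[1], d[2], min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
  cat(sprintf("  time : %d days (%s .. %s)\n", d[3],
              format(min(object@time)), format(max(object@time))))
  cat(sprintf("  mask : %d of %d pixels analyzed\n",
              sum(object@mask), length(object@mask)))
})

setMethod("show", "MMMGrid", function(object) {
  fin <- object@mmm[is.finite(object@mmm)]
  cat(sprintf("MMMGrid: %d lat x %d lon, MMM %.2f..%.2f degC (%d pixels)\n",
              length(object@lat), length(object@lon),
              if (length(fin)) min(fin) else NA,
              if (length(fin)) max(fin) else NA, length(fin)))
})

setMethod("show", "ReefPointSet", function(object) {
  cat(sprintf("ReefPointSet: %d points", nrow(object@coords)))
  if (length(object@region))
    cat(sprintf(" in %d regions", length(unique(object@region))))
  cat("\n")
})

setMethod("show", "ONISeries", function(object) {
  cat(sprintf("ONISeries: %d months (%s .. %s), range %.2f..%.2f degC\n",
              length(object@month), format(min(object@month), "%Y-%m"),
              format(max(object@month), "%Y-%m"),
              min(object@oni), max(object@oni)))
})

setMethod("show", "AnnualMaxGrid", function(object) {
  cat(sprintf(
    "AnnualMaxGrid: %d lat x %d lon x %d years (%d..%d), %d pixels masked\n",
    length(object@lat), length(object@lon), length(object@years),
    min(object@years), max(object@years), sum(object@mask)))
})

setMethod("show", "ExposureSummary", function(object) {
  ok <- object@mask
  cat("ExposureSummary over", sum(ok), "pixels\n")
  cat(sprintf("  max DHW        : %.2f degC-weeks (grid maximum)\n",
              suppressWarnings(max(object@maxDhw[ok], na.rm = TRUE))))
  cat(sprintf("  bleaching risk : threshold %.1f, %.0f%% of pixels with >= 1 event\n",
              object@bleachThr, 100 * mean(object@nBleaching[ok] >= 1,
                                           na.rm = TRUE)))
  cat(sprintf("  mortality risk : threshold %.1f, %.0f%% of pixels with >= 1 event\n",
              object@mortThr, 100 * mean(object@nMortality[ok] >= 1,
                                         na.rm = TRUE)))
})

setMethod("show", "RegionLabeling", function(object) {
  tab <- table(object@labels)
  cat(sprintf("RegionLabeling: k = %d over %d pixels\n",
              object@k, sum(!is.na(object@labels))))
  cat("  pixels per region:", paste(sprintf("%s:%d", names(tab), tab),
                                    collapse = " "), "\n")
})
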