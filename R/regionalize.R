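## Feature matrix for regionalization: one row per masked pixel with a
## complete annual-maximum record, columns = years, raw degC-weeks (no
## standardization: units are homogeneous across features).
.featureMatrix <- function(annualMax) {
  d <- dim(annualMax@values)
  npix <- d[1] * d[2]
  flat <- matrix(annualMax@values, nrow = npix)
  usable <- as.vector(annualMax@mask) & rowSums(!is.finite(flat)) == 0
  list(x = flat[usable, , drop = FALSE], idx = which(usable),
       nDropped = sum(annualMax@mask) - sum(usable))
}

#' Delineate heat-stress regions by K-means
#'
#' Clusters the per-pixel annual-maximum-DHW vectors with Lloyd's K-means
#' (best of `nInit` random restarts), then renumbers clusters by descending
#' mean of their center vectors, so region 1 is always the most exposed.
#' Pixels with any missing year are excluded from clustering (and counted).
#' First two principal-component scores of the feature matrix are attached
#' for diagnostic plotting.
#'
#' @param annualMax an [AnnualMaxGrid].
#' @param k number of regions.
#' @param seed RNG seed for the restarts (fixed seed = identical labeling).
#' @param nInit number of random restarts (default 25).
#' @return a [RegionLabeling].
#' @export
clusterRegions <- function(annualMax, k, seed = 1L, nInit = 25L) {
  stopifnot(is(annualMax, "AnnualMaxGrid"))
  fm <- .featureMatrix(annualMax)
  if (k > nrow(fm$x))
    stop("k = ", k, " exceeds the ", nrow(fm$x), " usable pixels")
  if (fm$nDropped > 0)
    message(fm$nDropped, " masked pixels dropped (incomplete annual record)")
  km <- withr::with_seed(as.integer(seed),
    .kmeansBest(fm$x, k, nInit))
  ord <- order(rowMeans(km$centers), decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labs <- relabel[km$cluster]
  d <- dim(annualMax@values)
  labels <- matrix(NA_integer_, d[1], d[2])
  labels[fm$idx] <- labs
  pca <- stats::prcomp(fm$x, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  rownames(scores) <- fm$idx
  new("RegionLabeling", labels = labels, k = as.integer(k),
      centers = km$centers[ord, , drop = FALSE],
      inertiaCurve = numeric(), pcaCoords = scores,
      years = annualMax@years)
}

.kmeansBest <- function(x, k, nInit) {
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1)
    return(list(cluster = rep(1L, nrow(x)), centers = ctr,
                tot.withinss = sum(sweep(x, 2, ctr[1, ])^2)))
  }
  u <- unique(x)
  if (nrow(u) <= k) {
    ## fewer distinct profiles than clusters: each distinct row is a center
    cl <- match(apply(x, 1, paste, collapse = "\r"),
                apply(u, 1, paste, collapse = "\r"))
    ctr <- u[c(seq_len(nrow(u)), rep(1L, k - nrow(u))), , drop = FALSE]
    return(list(cluster = cl, centers = ctr, tot.withinss = 0))
  }
  ## Lloyd can abort on an empty cluster in a degenerate restart;
  ## fall back to MacQueen, which reassigns incrementally
  suppressWarnings(tryCatch(
    stats::kmeans(x, centers = k, nstart = nInit, iter.max = 100L,
                  algorithm = "Lloyd"),
    error = function(e)
      stats::kmeans(x, centers = k, nstart = nInit, iter.max = 100L,
                    algorithm = "MacQueen")))
}

#' Elbow curve for choosing the number of heat-stress regions
#'
#' Computes the total within-cluster sum of squares (inertia) for
#' k = 1..`kMax` and suggests k at the maximum second difference of the
#' log-inertia curve — an automated stand-in for reading the elbow off the
#' plot. The log scale matters: on the raw curve the first drop dominates
#' whenever the between-cluster spread is large, biasing the argmax to
#' k = 2, whereas curvature of the log curve locates the last large
#' relative drop, which is what the eye picks out. The full curve is
#' always returned so the suggestion can be overridden. The suggestion is
#' flagged low-confidence when the contrast (maximum log-curvature) falls
#' below 0.5, as happens on unstructured data; planted block structure
#' sits far above the threshold and unstructured noise far below it.
#'
#' @param annualMax an [AnnualMaxGrid].
#' @param kMax largest k to evaluate (>= 3).
#' @param seed RNG seed.
#' @param nInit restarts per k (default 10).
#' @return `list(k = 1..kMax, inertia, suggestedK, contrast,
#'   lowConfidence)`.
#' @export
elbowCurve <- function(annualMax, kMax = 10L, seed = 1L, nInit = 10L) {
  stopifnot(is(annualMax, "AnnualMaxGrid"))
  kMax <- as.integer(kMax)
  if (kMax < 3L) stop("kMax must be >= 3")
  fm <- .featureMatrix(annualMax)
  kMax <- min(kMax, nrow(fm$x) - 1L)
  inertia <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(kMax), function(k)
      .kmeansBest(fm$x, k, nInit)$tot.withinss, numeric(1))
  })
  ## enforce monotonicity against rare restart luck
  inertia <- rev(cummax(rev(inertia)))
  d2 <- diff(diff(log(pmax(inertia, 1e-12))))  # curvature at k = 2..kMax-1
  suggestedK <- which.max(d2) + 1L
  contrast <- max(d2)
  list(k = seq_len(kMax), inertia = inertia, suggestedK = suggestedK,
       contrast = contrast, lowConfidence = contrast < 0.5)
}

#' Per-region annual exposure distributions
#'
#' For each heat-stress region and year, the median and interquartile range
#' of annual maximum DHW across the region's member pixels.
#'
#' @param labeling a [RegionLabeling].
#' @param annualMax the [AnnualMaxGrid] the labeling was built from.
#' @return data.frame with columns `region, year, median, q25, q75, n`.
#' @export
regionProfiles <- function(labeling, annualMax) {
  stopifnot(is(labeling, "RegionLabeling"), is(annualMax, "AnnualMaxGrid"))
  if (!all(dim(labeling@labels) == dim(annualMax@values)[1:2]))
    stop("labeling does not cover the grid")
  d <- dim(annualMax@values)
  flat <- matrix(annualMax@values, nrow = d[1] * d[2])
  labs <- as.vector(labeling@labels)
  out <- list()
  for (r in seq_len(labeling@k)) {
    rows <- which(!is.na(labs) & labs == r)
    if (!length(rows)) next
    sub <- flat[rows, , drop = FALSE]
    for (j in seq_along(annualMax@years)) {
      v <- sub[, j]
      v <- v[is.finite(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        region = r, year = annualMax@years[j],
        median = q[2], q25 = q[1], q75 = q[3], n = length(v))
    }
  }
  do.call(rbind, out)
}
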