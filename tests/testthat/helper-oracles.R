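## Independent oracles and fixture builders. Oracles are deliberately naive
## (loops, double sums) so they share no code path with the package.

## haversine distance in metres, spherical Earth R = 6371 km
oracleHaversine <- function(lon1, lat1, lon2, lat2) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

## brute-force per-day re-summation of the DHW definition
oracleDHW <- function(hsVec, windowDays = 84L, hsCutoff = 1,
                      maxMissingFrac = 0.1) {
  n <- length(hsVec)
  out <- rep(NA_real_, n)
  for (t in seq.int(windowDays, n)) {
    w <- hsVec[(t - windowDays + 1):t]
    if (mean(is.na(w)) > maxMissingFrac) next
    w <- w[!is.na(w)]
    out[t] <- sum(w[w >= hsCutoff]) / 7
  }
  out
}

## naive loop over the exposure metric definitions
oracleExposure <- function(annual, bleachThr = 4, mortThr = 8) {
  if (all(is.na(annual)))
    return(list(maxDhw = NA, nBleaching = NA, nMortality = NA,
                yearOfMax = NA))
  mx <- -Inf; ymx <- NA; nb <- 0L; nm <- 0L
  for (i in seq_along(annual)) {
    v <- annual[i]
    if (is.na(v)) next
    if (v > mx) { mx <- v; ymx <- i }
    if (v >= bleachThr) nb <- nb + 1L
    if (v >= mortThr) nm <- nm + 1L
  }
  list(maxDhw = mx, nBleaching = nb, nMortality = nm, yearOfMax = ymx)
}

## O(n^2) double-sum Pettitt statistic
oraclePettitt <- function(x) {
  n <- length(x)
  U <- numeric(n - 1)
  for (t in seq_len(n - 1)) {
    s <- 0
    for (i in 1:t) for (j in (t + 1):n) s <- s + sign(x[j] - x[i])
    U[t] <- s
  }
  K <- max(abs(U))
  list(K = K, tau = which.max(abs(U)),
       p = min(1, 2 * exp(-6 * K^2 / (n^3 + n^2))), U = U)
}

## month-counting ENSO phase oracle
oracleEnsoPhase <- function(oniYear, threshold = 0.05, minMonths = 5L) {
  warm <- oniYear > threshold
  cold <- oniYear < -threshold
  nW <- sum(warm); nC <- sum(cold)
  if (nW >= minMonths && (nC < minMonths || nW > nC)) return("ElNino")
  if (nC >= minMonths && (nW < minMonths || nC > nW)) return("LaNina")
  if (nW >= minMonths && nC >= minMonths && nW == nC) {
    mW <- mean(abs(oniYear[warm])); mC <- mean(abs(oniYear[cold]))
    if (mW > mC) return("ElNino")
    if (mC > mW) return("LaNina")
  }
  "Neutral"
}

## fixture: AnnualMaxGrid from an array
makeAnnualMaxGrid <- function(vals, nLat, nLon, nYears,
                              years = seq_len(nYears) + 1984L,
                              mask = matrix(TRUE, nLat, nLon)) {
  new("AnnualMaxGrid", years = as.integer(years),
      lat = 10 + seq_len(nLat) * 0.05, lon = -80 + seq_len(nLon) * 0.05,
      values = array(vals, c(nLat, nLon, nYears)), mask = mask,
      flagged = array(FALSE, c(nLat, nLon, nYears)))
}

## fixture: HotSpotCube from a pixel x time matrix
makeHotSpotCube <- function(flat, nLat, nLon,
                            start = as.Date("2000-01-01")) {
  nd <- ncol(flat)
  new("HotSpotCube", time = seq(start, by = "day", length.out = nd),
      lat = 10 + seq_len(nLat) * 0.05, lon = -80 + seq_len(nLon) * 0.05,
      values = array(flat, c(nLat, nLon, nd)),
      mask = matrix(TRUE, nLat, nLon), varname = "hs", units = "degC")
}

## fixture: three-block annual-max grid with distinct exposure histories
makeThreeBlockGrid <- function(nYears = 33L, noiseSD = 0.3) {
  profiles <- list(
    rep(8, nYears),                                      # chronic
    c(rep(0.5, nYears - 13), rep(8, 13)),                # emerging
    rep(0.5, nYears)                                     # refugium
  )
  base <- array(0, c(12, 12, nYears))
  for (y in seq_len(nYears)) {
    base[1:4, , y] <- profiles[[1]][y]
    base[5:8, , y] <- profiles[[2]][y]
    base[9:12, , y] <- profiles[[3]][y]
  }
  vals <- base + abs(rnorm(12 * 12 * nYears, sd = noiseSD))
  list(grid = makeAnnualMaxGrid(vals, 12, 12, nYears),
       truth = rep(rep(1:3, each = 4), times = 12))
}

## AR1 series with given innovation SD
ar1Series <- function(n, phi, sd) {
  as.numeric(stats::filter(rnorm(n, sd = sd), phi, method = "recursive"))
}
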