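#' Percentile filter for grouped samples
#'
#' Retains, within each group, the values lying inside that group's
#' `[lo, hi]` percentile interval (inclusive; R's default quantile
#' definition). Used before the robust ANOVA so that extreme pixels do not
#' dominate regional comparisons.
#'
#' @param samples named list of numeric vectors (one per group).
#' @param lo,hi percentile bounds as fractions (defaults 0.10 and 0.90).
#' @param minSize smallest allowed group size after filtering (default 10).
#' @return the filtered list.
#' @export
percentileFilter <- function(samples, lo = 0.10, hi = 0.90, minSize = 10L) {
  stopifnot(is.list(samples), length(samples) >= 1)
  out <- lapply(samples, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(v)
    q <- stats::quantile(v, c(lo, hi), names = FALSE)
    v[v >= q[1] & v <= q[2]]
  })
  small <- names(out)[vapply(out, length, integer(1)) < minSize]
  if (length(small))
    stop("groups below minimum size after filtering: ",
         paste(small, collapse = ", "))
  out
}

## trimmed mean, winsorized variance and the Yuen-style squared standard
## error d = (n-1) s^2_w / (h (h-1)) with h = n - 2 floor(trim n)
.trimStats <- function(v, trim) {
  n <- length(v)
  g <- floor(trim * n)
  h <- n - 2 * g
  sv <- sort(v)
  tm <- mean(sv[(g + 1):(n - g)])
  wv <- sv
  wv[wv < sv[g + 1]] <- sv[g + 1]
  wv[wv > sv[n - g]] <- sv[n - g]
  s2w <- stats::var(wv)
  list(n = n, h = h, tmean = tm, winvar = s2w,
       d = (n - 1) * s2w / (h * (h - 1)))
}

#' Heteroscedastic one-way ANOVA on trimmed means
#'
#' Welch-type one-way test on `trim`-trimmed group means with winsorized
#' variances (the robust heteroscedastic construction of Wilcox), plus all
#' pairwise trimmed-mean contrasts. Pairwise tests are Yuen-Welch
#' comparisons with Sidak familywise adjustment and simultaneous confidence
#' intervals at the adjusted level. With `trim = 0` the omnibus test
#' reduces exactly to the classical Welch ANOVA.
#'
#' @param samples named list of numeric vectors, >= 2 groups.
#' @param trim trimming proportion per tail (default 0.10).
#' @param conf familywise confidence level for the post hoc intervals
#'   (default 0.95).
#' @return list with `F` (the heteroscedastic statistic), `df1`, `df2`
#'   (fractional), `p`, `trim`, and `posthoc`: a data.frame with one row
#'   per unordered pair (`group1, group2, diff, se, df, ci.lower, ci.upper,
#'   p, p.adj, significant`).
#' @export
trimmedAnova <- function(samples, trim = 0.10, conf = 0.95) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  samples <- lapply(samples, function(v) v[is.finite(v)])
  J <- length(samples)
  st <- lapply(samples, function(v) {
    if (length(v) < 5) stop("group with fewer than 5 values")
    s <- .trimStats(v, trim)
    if (s$winvar <= 0)
      stop("degenerate variance: a group is constant after trimming")
    s
  })
  w <- vapply(st, function(s) 1 / s$d, numeric(1))
  U <- sum(w)
  xt <- vapply(st, `[[`, numeric(1), "tmean")
  xtilde <- sum(w * xt) / U
  A <- sum(w * (xt - xtilde)^2) / (J - 1)
  hs <- vapply(st, `[[`, numeric(1), "h")
  B <- 2 * (J - 2) / (J^2 - 1) * sum((1 - w / U)^2 / (hs - 1))
  Fstat <- A / (1 + B)
  df1 <- J - 1
  df2 <- 1 / (3 / (J^2 - 1) * sum((1 - w / U)^2 / (hs - 1)))
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(J, 2)
  C <- ncol(pairs)
  alphaAdj <- 1 - conf^(1 / C)   # Sidak: per-pair level for FWE conf
  ph <- lapply(seq_len(C), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sa <- st[[a]]; sb <- st[[b]]
    diff <- sa$tmean - sb$tmean
    se <- sqrt(sa$d + sb$d)
    dfp <- (sa$d + sb$d)^2 /
      (sa$d^2 / (sa$h - 1) + sb$d^2 / (sb$h - 1))
    tval <- diff / se
    praw <- 2 * stats::pt(abs(tval), dfp, lower.tail = FALSE)
    crit <- stats::qt(1 - alphaAdj / 2, dfp)
    data.frame(group1 = names(samples)[a], group2 = names(samples)[b],
               diff = diff, se = se, df = dfp,
               ci.lower = diff - crit * se, ci.upper = diff + crit * se,
               p = praw, p.adj = min(1, 1 - (1 - praw)^C))
  })
  posthoc <- do.call(rbind, ph)
  posthoc$significant <- posthoc$p.adj < (1 - conf)
  list(F = Fstat, df1 = df1, df2 = df2, p = p, trim = trim,
       posthoc = posthoc)
}
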