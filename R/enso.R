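#' Classify ENSO phases by year from the ONI
#'
#' Assigns each calendar year its dominant ENSO phase: months with anomaly
#' above `+threshold` count toward El Nino, below `-threshold` toward
#' La Nina, and a phase is assigned only when its qualifying-month count
#' reaches `minMonths`. When both phases qualify the larger count wins; an
#' exact tie falls back to the larger mean absolute anomaly among the
#' qualifying months, and a full tie is Neutral. The default threshold is
#' 0.05 degC (configurable: the conventional ONI cutoff is 0.5 degC).
#'
#' @param oni an [ONISeries] covering whole years.
#' @param threshold phase threshold in degC (default 0.05).
#' @param minMonths qualifying-month minimum (default 5).
#' @return data.frame `year, phase` (factor with levels Neutral, ElNino,
#'   LaNina — Neutral first so model contrasts read against it),
#'   `nWarm, nCold`.
#' @export
classifyEnso <- function(oni, threshold = 0.05, minMonths = 5L) {
  stopifnot(is(oni, "ONISeries"))
  yr <- as.integer(format(oni@month, "%Y"))
  years <- sort(unique(yr))
  cnt <- table(yr)
  bad <- names(cnt)[cnt != 12L]
  if (length(bad))
    stop("partial years in ONI series: ", paste(bad, collapse = ", "))
  out <- lapply(years, function(y) {
    v <- oni@oni[yr == y]
    warm <- v > threshold
    cold <- v < -threshold
    nW <- sum(warm)
    nC <- sum(cold)
    phase <- "Neutral"
    qW <- nW >= minMonths
    qC <- nC >= minMonths
    if (qW && !qC) phase <- "ElNino"
    else if (qC && !qW) phase <- "LaNina"
    else if (qW && qC) {
      if (nW > nC) phase <- "ElNino"
      else if (nC > nW) phase <- "LaNina"
      else {
        mW <- mean(abs(v[warm])); mC <- mean(abs(v[cold]))
        if (mW > mC) phase <- "ElNino"
        else if (mC > mW) phase <- "LaNina"
        # full tie stays Neutral
      }
    }
    data.frame(year = y, phase = phase, nWarm = nW, nCold = nC)
  })
  res <- do.call(rbind, out)
  res$phase <- factor(res$phase, levels = c("Neutral", "ElNino", "LaNina"))
  res
}

#' Annual hottest monthly average DHW
#'
#' Reduces a regional monthly DHW series to one value per calendar year:
#' the maximum of that year's monthly means — the dependent variable of the
#' annual trend models. Years without full monthly coverage are dropped
#' with a warning.
#'
#' @param monthly data.frame `region, month, value` from [monthlyMean()],
#'   or `month, value` for a single region.
#' @return data.frame `region, year, value` (region constant if absent in
#'   the input).
#' @export
annualStress <- function(monthly) {
  if (!"region" %in% names(monthly)) monthly$region <- 1L
  stopifnot(all(c("month", "value") %in% names(monthly)))
  yr <- as.integer(format(as.Date(monthly$month), "%Y"))
  agg <- stats::aggregate(monthly$value,
                          by = list(region = monthly$region, year = yr),
                          FUN = function(v) sum(!is.na(v)))
  partial <- agg$x < 12L
  if (any(partial))
    warning(sum(partial), " region-years without full monthly coverage ",
            "dropped")
  mx <- stats::aggregate(monthly$value,
                         by = list(region = monthly$region, year = yr),
                         FUN = max, na.rm = TRUE)
  names(mx)[3] <- "value"
  mx <- mx[!partial, ]
  mx[order(mx$region, mx$year), ]
}

## AICc from a fitted model's log-likelihood
.aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- attr(ll, "nobs")
  if (is.null(n)) n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Gamma GLM for annual heat stress with ENSO phase terms
#'
#' Fits a Gamma generalized linear model with log link to the annual
#' hottest monthly average DHW, linear predictor
#' `intercept + year + phase` (additive; phase baseline = Neutral). The
#' sequential analysis of deviance tests the year term and then the phase
#' term with F tests; residual degrees of freedom count the estimated Gamma
#' dispersion as a parameter, so with n years the table reports
#' `(1, n - 3)` for the year term and `(2, n - 5)` for a 3-level phase
#' factor. Zero responses are shifted by `eps` (the Gamma family requires
#' positive values); the shift is recorded in the result.
#'
#' @param annual data.frame `year, value` ([annualStress()] output, one
#'   region).
#' @param phases data.frame `year, phase` from [classifyEnso()].
#' @param eps shift applied to non-positive values (default 1e-3).
#' @return list with `fit` (the glm), `coef`, `devianceTable` (terms, df,
#'   dfr, residual deviance, F, p), `explainedDeviance`, `aicc`,
#'   `residLag1` (lag-1 autocorrelation of Pearson residuals), `eps`,
#'   `kind = "GLM-Gamma-log"`.
#' @export
fitStressGLM <- function(annual, phases, eps = 1e-3) {
  df <- merge(annual, phases[, c("year", "phase")], by = "year")
  if (!nrow(df)) stop("no overlapping years between stress and phases")
  y <- df$value
  if (any(y <= 0)) {
    warning(sum(y <= 0), " non-positive annual values shifted by ", eps)
    y <- y + eps
  }
  if (any(y <= 0)) stop("non-positive response after shift")
  df$y <- y
  df$phase <- stats::relevel(factor(df$phase), ref = "Neutral")
  n <- nrow(df)
  if (stats::sd(y) == 0) {
    ## constant response: null model; likelihood-based AICc undefined
    cf <- c(log(y[1]), 0, 0, 0)
    names(cf) <- c("(Intercept)", "year",
                   paste0("phase", setdiff(levels(df$phase), "Neutral")))
    dfs <- c(1L, nlevels(df$phase) - 1L)
    dfr <- n - c(2L, 2L + dfs[2]) - 1L
    tab <- data.frame(term = c("Null", "Years", "ENSO"),
                      df = c(NA, dfs), dfr = c(n - 1L, dfr),
                      residDeviance = c(0, 0, 0), F = c(NA, 0, 0),
                      p = c(NA, 1, 1))
    return(list(fit = NULL, coef = cf, devianceTable = tab,
                explainedDeviance = 0, aicc = NA_real_,
                residLag1 = NA_real_, eps = eps, kind = "GLM-Gamma-log"))
  }
  m0 <- stats::glm(y ~ 1, family = stats::Gamma(link = "log"), data = df)
  m1 <- stats::glm(y ~ year, family = stats::Gamma(link = "log"),
                   data = df)
  m2 <- stats::glm(y ~ year + phase, family = stats::Gamma(link = "log"),
                   data = df)
  disp <- summary(m2)$dispersion
  devs <- c(stats::deviance(m0), stats::deviance(m1), stats::deviance(m2))
  dfs <- c(1L, nlevels(df$phase) - 1L)
  ## residual df counts the dispersion parameter: n - p_cum - 1
  pcum <- c(2L, 2L + dfs[2])
  dfr <- n - pcum - 1L
  Fstat <- (-diff(devs) / dfs) / disp
  Fstat[!is.finite(Fstat)] <- 0          # 0/0 when the response is constant
  pval <- stats::pf(Fstat, dfs, dfr, lower.tail = FALSE)
  tab <- data.frame(
    term = c("Null", "Years", "ENSO"),
    df = c(NA, dfs),
    dfr = c(n - 1L, dfr),
    residDeviance = devs,
    F = c(NA, Fstat),
    p = c(NA, pval)
  )
  list(fit = m2, coef = stats::coef(m2), devianceTable = tab,
       explainedDeviance = 1 - devs[3] / devs[1],
       aicc = .aicc(m2),
       residLag1 = .residLag1(stats::residuals(m2, type = "pearson")),
       eps = eps, kind = "GLM-Gamma-log")
}

.residLag1 <- function(r) {
  if (length(r) < 3 || stats::sd(r) == 0) return(NA_real_)
  stats::acf(r, plot = FALSE, lag.max = 1)$acf[2]
}

#' AR1 GLS for annual heat stress with ENSO phase terms
#'
#' The Gaussian counterpart of [fitStressGLM()]: generalized least squares
#' with AR1 errors and the same additive `year + phase` terms, fitted by
#' maximum likelihood so its AICc is comparable with the GLM's.
#'
#' @inheritParams fitStressGLM
#' @return list with `fit`, `coef`, `anovaTable` (sequential F tests),
#'   `aicc`, `residLag1` (lag-1 autocorrelation of normalized residuals),
#'   `phi` (estimated AR1 parameter), `kind = "GLS-AR1"`.
#' @export
fitStressGLS <- function(annual, phases) {
  df <- merge(annual, phases[, c("year", "phase")], by = "year")
  if (!nrow(df)) stop("no overlapping years between stress and phases")
  df$phase <- stats::relevel(factor(df$phase), ref = "Neutral")
  df$y <- df$value
  if (stats::sd(df$y) == 0) {
    ## constant response: no trend, nothing to model
    cf <- c(df$y[1], 0, 0, 0)
    names(cf) <- c("(Intercept)", "year",
                   paste0("phase", setdiff(levels(df$phase), "Neutral")))
    return(list(fit = NULL, coef = cf,
                anovaTable = data.frame(term = character(), df = integer(),
                                        F = numeric(), p = numeric()),
                aicc = NA_real_, residLag1 = NA_real_, phi = NA_real_,
                kind = "GLS-AR1"))
  }
  fit <- tryCatch(
    nlme::gls(y ~ year + phase, data = df,
              correlation = nlme::corAR1(form = ~year), method = "ML"),
    error = function(e) stop("GLS fit failed: ", conditionMessage(e)))
  phi <- tryCatch(
    stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE),
    error = function(e) NA_real_)
  at <- stats::anova(fit)
  list(fit = fit, coef = stats::coef(fit),
       anovaTable = data.frame(term = rownames(at),
                               df = at$numDF, F = at$`F-value`,
                               p = at$`p-value`),
       aicc = .aicc(fit),
       residLag1 = .residLag1(stats::residuals(fit, type = "normalized")),
       phi = unname(phi), kind = "GLS-AR1")
}

#' Compare the Gamma-GLM and AR1-GLS annual trend models
#'
#' Reports both models' AICc, their difference, and the lag-1
#' autocorrelation of each model's residuals; the model with the lower AICc
#' is selected (an exact tie reports no selection). The comparison uses
#' each model's own likelihood — a heuristic when the likelihoods belong to
#' different families, as flagged in the report.
#'
#' @param glmRes result of [fitStressGLM()].
#' @param glsRes result of [fitStressGLS()].
#' @return list `table` (kind, AICc, residLag1), `deltaAICc`
#'   (GLS - GLM), `selected` (`"GLM-Gamma-log"`, `"GLS-AR1"` or `NA` on a
#'   tie), `note`.
#' @export
compareStressModels <- function(glmRes, glsRes) {
  tab <- data.frame(
    kind = c(glmRes$kind, glsRes$kind),
    AICc = c(glmRes$aicc, glsRes$aicc),
    residLag1 = c(glmRes$residLag1, glsRes$residLag1)
  )
  dA <- glsRes$aicc - glmRes$aicc
  selected <- if (abs(dA) < 1e-10) NA_character_
              else if (dA > 0) glmRes$kind else glsRes$kind
  list(table = tab, deltaAICc = dA, selected = selected,
       note = paste("AICc compared across different likelihood families;",
                    "treat the comparison as heuristic"))
}
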