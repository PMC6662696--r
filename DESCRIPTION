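Package: reefheat
Title: Degree Heating Weeks and Heat-Stress Regionalization for Coral Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes coral bleaching HotSpots and Degree Heating Weeks (DHW)
    from gridded daily sea-surface temperature and a Maximum Monthly Mean
    climatology, derives per-pixel heat-stress exposure indicators (maximum
    DHW, bleaching- and mortality-risk event frequencies, year of maximum,
    AR1 generalized-least-squares trends), delineates heat-stress regions by
    K-means clustering of annual-maximum-DHW histories with elbow and PCA
    diagnostics, and analyses regional temporal dynamics: Pettitt change
    points, Morlet wavelet and bias-corrected cross-wavelet coupling to the
    Oceanic Nino Index, lagged cross-correlation, ENSO phase classification,
    and Gamma-GLM versus AR1-GLS annual trend models compared by AICc.
    Includes a synthetic SST scenario generator with seasonal cycle, warming
    trend, AR1 noise, block exposure regimes and lagged ENSO forcing, plus
    robust heteroscedastic trimmed-means ANOVA for regional comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nlme,
    geosphere,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
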