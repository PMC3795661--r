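Package: scalescape
Title: Scale-Specific Time Series Modelling of Community Dynamics and
    Relative Resilience of Alternative Ecological States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the relative resilience of alternative ecological states
    from multispecies time series. Alternative states are delimited on a
    univariate driver with a sequential t-test regime-shift detector (STARS);
    temporal structure within each state is modelled by redundancy analysis
    of the Hellinger-transformed community matrix on asymmetric-eigenvector-map
    (AEM) temporal eigenfunctions, with permutation-based forward selection
    and sequential tests of the canonical axes; species are attributed to the
    significant axes by Spearman rank correlation, separating scale-tracking
    taxa from stochastic ones. Per-sample community metrics (richness, Shannon
    diversity and its number equivalent, evenness, total biovolume) and a
    balanced repeated-measures ANOVA with Huynh-Feldt correction are provided,
    together with a synthetic-data generator that emulates the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite
Config/testthat/edition: 3
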