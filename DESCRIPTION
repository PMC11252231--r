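Package: soiltrace
Title: Trace-Element Pollution, Ecological and Health Risk Assessment for
    Soils with APCS-MLR Source Apportionment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of trace-element contamination in agricultural soils
    from per-site concentration tables. Computes the classical pollution
    indices (contamination factor, geoaccumulation index, enrichment factor,
    pollution load index, Nemerow pollution index), Hakanson ecological risk
    indices (Er, RI and the Nemerow risk index), USEPA residential health
    risks (hazard quotients and carcinogenic risks for ingestion, dermal and
    inhalation routes, for child, adult and age-adjusted lifetime receptors),
    and source apportionment by the absolute principal component
    scores-multiple linear regression (APCS-MLR) receptor model with varimax
    rotation and Kaiser retention. Ships upper-continental-crust backgrounds,
    soil guideline values and toxicity constants, a synthetic geochemical
    mixing simulator with known source structure for validation, and a
    one-call pipeline writing a full report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
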