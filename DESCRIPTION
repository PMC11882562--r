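Package: meteocat
Title: Meteorological Drivers of Tea Catechin Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links seasonal meteorological conditions to catechin accumulation
    in tea (Camellia sinensis). Provides meteorological feature construction
    (effective accumulated temperature, rainy-day mean rainfall), partial
    least squares regression with Variable Importance in Projection (VIP)
    screening of eight weather factors, per-catechin linear calibration
    models with RMSEC/RMSECV/RMSEP validation, exact grouped linear
    programming to find weather conditions maximising predicted catechin
    concentrations, 2^-ddCt qPCR expression processing with hierarchical
    clustering, correlation and principal component summaries, and a
    synthetic-data generator emulating a multi-site, multi-season plantation
    survey so the whole chain is testable without field data. Ships the
    published regression equations for cv. Tieguanyin as a reference fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
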