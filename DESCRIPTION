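Package: peatsense
Title: Coupled Organic Geochemistry and Remote Sensing of Tropical Peatland Condition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing tropical peat swamp forest condition by
    coupling Rock-Eval (6) pyrolysis organic geochemistry with optical
    remote sensing. Computes thermal-stability indices (the Sebag R- and
    I-indices) from S2 pyrograms, bulk density and carbon stocks from
    peat-core records, normalised burn ratio (NBR) time-series statistics
    from multi-year reflectance rasters, and relates upper-profile peat
    condition to the remotely sensed products with rank-based statistics.
    Includes a synthetic-data generator that emulates pristine and
    disturbed peat decomposition profiles so the full pipeline can be
    exercised and tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
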