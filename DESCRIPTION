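Package: nutriclinr
Title: Nutricline Depth Trends from Hydrographic Bottle Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying long-term trends in ocean nutricline
    depths from archives of hydrographic bottle casts. The nitracline and
    phosphacline are located per cast by linear interpolation of nitrate
    and phosphate profiles to Redfield-paired threshold concentrations;
    casts are aggregated to 1-degree sites and annual means, site-specific
    depth trends are estimated by ordinary least squares, and global and
    regional median trends are summarised with percentile bootstrap
    confidence intervals. A battery of robustness procedures is included:
    scrambled-year permutation nulls for median trends, bottle-level
    measurement-error injection, climatology-sampling simulations with
    imposed artificial trends, trend-distribution matching, paired
    nitracline-minus-phosphacline residual trends, density-at-nutricline
    trends, and a deep-water concentration-bias diagnostic. A synthetic
    cruise-archive generator with analytic ground truth makes every stage
    testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
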