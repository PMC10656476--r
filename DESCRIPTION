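Package: citypop
Title: City-Level Cohort-Component Population Projection under
    Fertility and Migration Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Annual cohort-component projection of a multi-city population
    system from a baseline census year to 2100.  Implements city-level
    births from age-specific fertility and a sex ratio at birth, survival
    from age- and sex-specific mortality calibrated to life-expectancy
    targets, and a two-level net-migration module in which provincial and
    city net flows are computed from rates and rebalanced so that
    inter-provincial migration sums to zero and city flows aggregate to
    their province.  Ships a 5 fertility x 3 migration scenario grid with
    tier- and region-specific migration multipliers and policy overlays
    (population ceilings, settlement-reform reductions for small and
    middle-sized cities), APE/PE projection-error reports, a seeded
    synthetic-baseline generator, and writers for the published CSV
    layout.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
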