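Package: kinproj
Title: Time-Varying Matrix Kinship Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the expected age-sex structure of the kinship network of a
    female focal individual from period age-specific fertility and survival
    schedules, using Leslie-type matrix kinship models with time-varying rates
    and a two-sex androgynous approximation. Includes a synthetic-rate
    generator emulating probabilistic demographic projection ensembles, a
    genealogical microsimulation oracle for validation, and a pipeline that
    derives family-size and kin-age summary metrics with median and 80%
    projection intervals and population-weighted regional aggregates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
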