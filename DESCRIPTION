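Package: nichecarve
Title: Refine Ecological Niche Models with Land-Class and Edaphic Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolset for environmental niche model (ENM) output
    on ESRI ASCII grids. Trims a continuous habitat-suitability surface to an
    approximate realized distribution by thresholding and by filtering against
    up to three categorical or continuous feature rasters (e.g. soil class,
    elevation), classifies temporal corridors between baseline and projected
    climate suitability (unsuitable / baseline-only / both / projected-only),
    projects the result onto a finer-resolution categorical land-class model by
    appending synthetic classes above the model's highest class, and quantifies
    per-class cell counts and square-kilometre areas globally and over a tile
    grid using a spherical latitude-band area formula. Includes a deterministic
    synthetic-fixture generator, tidy report tibbles with broom-style tidy()
    and glance() methods, ggplot2 autoplot() methods, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
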