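Package: epimech
Title: Quantitative Analysis of Tight-Junction Assembly and Epithelial Cell
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based and tabular quantification pipelines for epithelial
    tight-junction biology and cell mechanics: junctional intensity indices
    from line and region annotations, cell and focal-adhesion morphometry,
    bright-field island morphogenesis metrics, traction force microscopy by
    unconstrained Fourier-transform traction cytometry with strain-energy
    densities, three-filter sensitized-emission FRET with crossover
    correction, freeze-fracture tight-junction strand morphometry, and
    epithelial barrier statistics (transepithelial resistance, apparent
    permeability, two-proportion tests with Holm adjustment). A synthetic-data
    generator produces ground-truthed fixtures for every pipeline so each
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
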