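Package: fespec
Title: Thermodynamic Iron Speciation and Partitioning in Subsurface Seawater
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A thermodynamically consistent speciation engine for iron in
    subsurface seawater. Partitions total labile iron across four equilibrium
    pathways: binding to heterogeneous dissolved organic matter (NICA-Donnan),
    complexation by a discrete siderophore ligand (ferrioxamine B proxy),
    precipitation of authigenic ferric oxyhydroxide at the ferrihydrite
    solubility cap, and reversible binding to particulate organic matter
    (a second NICA-Donnan phase). Includes a transect-scale analysis pipeline
    (unit conversions, gridding, predicted dissolved/particulate iron
    partitioning, effective binding affinities of occupied sites, residual
    classification against equilibrium), extended optimum multiparameter
    water-mass analysis, and a seedable synthetic-transect generator for
    end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    geosphere,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
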