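Package: markushcov
Title: Chemical-Space Coverage Analysis of Markush Combinatorial Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates combinatorial libraries from Markush definitions
    (scaffold plus per-position substituent lists), builds reduced-dimension
    chemical spaces from molecular descriptors via principal component
    analysis, partitions those spaces with hierarchical, relocation and
    cell-based (binning) methods, and quantifies how well a compound subset
    represents the full library using space-coverage and population-coverage
    statistics, with analytic and Monte-Carlo random-sampling baselines and
    rational one-per-partition selection. Includes a synthetic scenario
    generator emulating hit-focused analog series for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Open Babel (obabel on the PATH) for SMILES
    canonicalization and descriptor calculation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
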