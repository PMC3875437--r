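Package: rheoscan
Title: Rheostat and Toggle Position Classification from Parallel
    Mutagenesis of Protein Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for site-saturation mutagenesis carried out
    in parallel across protein homologs, modeled on reporter-assay scans of
    the LacI/GalR linker. Normalizes per-variant repression against each
    parent protein, applies a dual fold-change/standard-deviation criterion
    for functional change, and classifies every (homolog, position) as a
    rheostat, toggle, or neutral location from the rank-ordered substitution
    outcomes. Computes gap-inclusive Shannon sequence entropies over
    motif-defined alignment subsets to separate toggle from rheostat
    candidates, cross-tabulates substitution outcomes against natural
    amino-acid frequencies, and screens outcomes against physico-chemical
    scales. A seeded synthetic-data generator with ground-truth position
    classes makes every stage testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
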