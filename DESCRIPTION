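Package: frontassembly
Title: Community Assembly and Functional Diversity of Phytoplankton Across a Tidal Front
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse eukaryotic phytoplankton metabarcoding surveys of
    frontal systems: diversity partitioning (richness, analytic rarefaction,
    Chao1, occurrence and abundance classes), OTU-connectivity networks with a
    curated-richness control, phylogenetic null-model inference of community
    assembly processes (beta-mean-nearest-taxon distance, beta-nearest-taxon
    index, Raup-Crick, and the five-process classification), PERMANOVA of
    turnover against environmental gradients, and trait-based functional
    diversity (Gower distance, principal coordinate analysis, convex-hull
    functional richness, ecological-strategy clustering). Ships a synthetic
    metacommunity generator with phylogenetically heritable niches and traits,
    environmental gradients with a frontal nutrient pulse, and tunable
    selection, dispersal and drift, so the full pipeline runs and is testable
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    vegan,
    cluster,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
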