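Package: lectiscope
Title: Discovery of Uncharacterized Microbial Lectins from Domain
    Annotations, Metagenomic Catalogs and Glycan Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines candidate microbial lectins from domain-annotated
    protein sets (carbohydrate-binding module present, no catalytic
    domain, curated keyword exclusions), collapses them into unique
    sequences by greedy centroid clustering at a percent-identity
    threshold, scores their presence across per-sample metagenomic gene
    catalogs into a Boolean incidence matrix with body-site prevalence,
    overlap and analytic sample-based rarefaction, and analyses glycan
    microarray screens: replicate trimming, top-binder normalization,
    binder calling and mining of conserved glycan-binding motifs from
    condensed-notation glycan structures. Includes seeded synthetic-data
    generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
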