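Package: introscan
Title: Detection and Genetic Mapping of Alien Chromosomal Introgressions
    from SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Locates alien chromosomal introgressions in polyploid wheat
    from species-diagnostic SNP patterns, assigns the donor lineage with a
    neighbor-joining phylogeny built from genotype p-distances, genetically
    maps linked dominant rust-resistance loci in F2/F3 populations via
    segregation chi-square tests and minimal recombinant-gamete counting,
    and evaluates CAPS and InDel diagnostic markers by in-silico
    restriction digestion with degenerate (IUPAC) recognition sites.
    Seeded simulators generate multi-species SNP panels, mapping
    populations, and marker amplicons with ground-truth bookkeeping so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
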