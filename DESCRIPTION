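Package: gluhap
Title: Molecular Haplotype Analysis of the Two-Gene Glu-D1 Glutenin Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular haplotype analysis of the high-molecular-weight
    glutenin locus Glu-D1, a pair of tightly linked genes (the x and y subunits)
    on chromosome 1D, across structured diploid panels of Aegilops tauschii.
    Provides depth-ratio genotype calling from VCF DP/DV annotations, site
    filtering, exact-match haplotype grouping with clade-based nomenclature,
    detection of rare x/y recombinant haplotypes, additive-relationship
    (VanRaden) distance clustering, synonymous/non-synonymous effect annotation
    with a cysteine-residue audit, lineage-specific k-mer bin classification
    with gene colocalization, and a Mantel test of isolation by distance.
    Includes a synthetic-panel generator with planted truth (lineages,
    haplotype pools, recombinants, duplicates, sequencing noise) so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    geosphere,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
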