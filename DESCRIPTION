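Package: karyomorph
Title: Karyomorphometric Analysis and Cytotaxonomic Comparison of Plant
    Karyotypes
Version: 0.1.0
Authors@R:
    person("Piotr", "Lis", email = "piotr.lis@posteo.net", role = c("aut", "cre"))
Description: Tools for karyomorphometric analysis of mitotic metaphase
    chromosome measurements: homolog pairing and mean haploid karyotype
    construction, Levan centromere-position classification, karyotype
    formulae, total haploid chromosome length and length range, the
    asymmetry indices CV(CL), CV(CI) and M(CA), Stebbins symmetry classes,
    and idiogram rendering.  Accession-level karyotype parameter tables
    feed distance-based cytotaxonomy: UPGMA clustering with cophenetic
    correlation, Gower-similarity principal coordinate analysis, and
    asymmetry scatter plots.  A seeded synthetic-measurement generator
    with known ground truth makes every pipeline stage testable without
    raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
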