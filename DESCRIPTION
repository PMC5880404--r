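Package: hazelmap
Title: Pseudo-Testcross Linkage Mapping, Translocation Disentanglement and
    QTL Scanning for Outcrossing F1 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genetic analysis of F1 full-sib mapping populations of
    highly heterozygous outcrossing species, built around the double
    pseudo-testcross strategy. Classifies biallelic SNPs by parental state,
    tests 1:1 segregation with tiered distortion classes, removes redundant
    markers, estimates two-point recombination fractions and LOD scores,
    groups and orders markers into parent-specific linkage maps with Kosambi
    distances, detects and disentangles 'pseudo-linkage' caused by a
    reciprocal translocation heterozygous in one parent (principal
    coordinate visualisation, breakpoint localisation, splitting the progeny
    into translocated and normal subpopulations, reconstruction of the four
    chromosome arms), and scans for quantitative trait loci by Kruskal-Wallis
    marker tests, Haley-Knott simple interval mapping and multiple-QTL
    mapping with cofactor backward elimination and permutation-based
    genome-wide thresholds. A meiosis simulator for translocation
    heterozygotes generates fully specified synthetic populations with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
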