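Package: hybriscope
Title: Hybrid Lineage Inference from Dominant Markers, Plastid Haplotypes
    and Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the origin of allopolyploid hybrid
    lineages from multi-marker evidence, modelled on the workflow used for
    apomictic Potentilla complexes. Covers AFLP-style binary fragment
    matrices (fragment totals, shared and private fragments, replicate
    repeatability), threshold-based clone assignment with bias-corrected
    Nei genotype diversity, plastid haplotype coding and statistical
    parsimony networks with a connection limit, Jaccard distances with
    Neighbor-Net circular split systems, group-anchored two-dimensional
    ordination with a mapping-error statistic, DNA ploidy attribution from
    flow-cytometry fluorescence ratios, and a gamete-ploidy
    cross-enumeration test of single- versus multiple-event hybrid origin.
    A seeded synthetic-data generator emulates the statistical structure
    of such datasets (taxon band-frequency profiles, clonal replication
    with scoring error, hybrid band additivity with band loss and de novo
    gain, maternal haplotype inheritance, gamete-sum ploidies) so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
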