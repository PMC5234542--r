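Package: aflpdelimit
Title: Genetic Cluster Delimitation from AFLP Profiles and Sequence Characters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to delimit genetic clusters from dominant AFLP markers and
    companion sequence data. Implements fragment-analyzer peak binning,
    sum-of-signal normalisation and three-state (absent/ambiguous/present)
    genotype calling, replicate-based scoring-error quantification with a
    two-step error-elimination filter, p-distances with pairwise-complete
    handling of ambiguous calls, NeighborNet circular orderings with
    non-negative least-squares split weights written as SplitsTree-compatible
    NEXUS, simple indel coding of alignment gaps, Fitch parsimony with exact
    branch-and-bound and heuristic searches plus nonparametric bootstrap, and
    seeded synthetic-data generators (AFLP peak tables with replicate noise
    from binning and threshold effects; sequence alignments evolved on a known
    tree) so every pipeline stage can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
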