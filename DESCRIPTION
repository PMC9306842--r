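Package: gmycsampler
Title: Taxon-Resampling Sensitivity Analysis for GMYC Species Delimitation
Version: 0.1.0
Authors@R:
    person("gmycsampler", "maintainers", email = "gmycsampler@example.org",
           role = c("aut", "cre"))
Description: Tools to assess how taxon sampling and singletons affect
    single-locus species delimitation with the generalized mixed
    Yule-coalescent (GMYC) model. Provides random subsampling of sequence
    alignments without replacement (optionally guaranteeing at least one
    representative per predefined morphospecies or ecotype), a
    single-threshold GMYC fit on ultrametric trees (maximum-likelihood
    threshold scan with a likelihood-ratio test against a one-class null),
    concordance metrics between GMYC species and user-predefined groups
    (merges, splits, exact matches, percentage match with and without
    singletons, splitting ratios, per-group oversplit factors), ensemble
    summaries and accumulation-curve data across subset fractions, and a
    synthetic-data generator (Yule species trees, within-species
    coalescent gene trees, JC69 sequences) with known true labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
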