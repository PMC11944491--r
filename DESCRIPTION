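Package: otutiers
Title: Tiered OTU Clustering and Diversity Estimation for Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organising taxonomically labelled 16S rRNA amplicon OTU
    sequences into nested molecular species, genus and family clusters at
    calibrated percent-identity thresholds. Provides a semi-global pairwise
    identity kernel with free terminal gaps, greedy centroid clustering,
    reference-based sequence replacement, identity-threshold calibration from
    labelled reference sets, conservative diversity lower bounds, rarefaction
    and per-sample discovery rates, environment novelty scores, and
    occupancy-stratified verification of cluster representatives against a
    second sequence collection. A hierarchical synthetic community simulator
    with ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
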