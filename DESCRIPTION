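Package: hemidyn
Title: Hemispheric Dynamics of Visual Object Coding from Time-Resolved EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual object information is represented
    within and shared across the two cerebral hemispheres using time-resolved
    multivariate decoding of epoched EEG. Provides a synthetic generator for
    lateralized rapid serial visual presentation experiments with known
    interhemispheric transfer structure; pairwise linear-discriminant decoding
    within occipito-temporal electrode clusters at 1-ms resolution;
    split-half time-by-time representational similarity analysis with
    transfer-delay profiles and asymmetry tests; behavioral dissimilarity
    estimation from triplet odd-one-out judgments; commonality
    (variance-partitioning) analysis of neural dissimilarities against
    behavioral models with stimulus-label permutation nulls; and
    Jeffreys-Zellner-Siow interval-null Bayes factors with sustained-evidence
    onset detection and leave-two-out jackknife confidence intervals.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
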