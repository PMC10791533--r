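Package: kinavoid
Title: Genotype-Likelihood Relatedness and Inbreeding-Avoidance Inference
    in Closed Study Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inbreeding risk and inbreeding avoidance in
    long-term field studies of group-living animals. Estimates pairwise
    genetic relatedness from sequencing genotype likelihoods via maximum
    likelihood over the nine condensed Jacquard identity coefficients
    (Hedrick-Lacy relatedness), computes pedigree kinship and relatedness
    by recursion, derives demography quantities (conception dates,
    philopatry rates, actual versus potential parent pairs under a
    random-mating null), and fits a dyadic logit-link beta regression
    mixed model with multi-membership individual effects by MCMC. A
    community simulator with tunable female philopatry, immigration and
    mate-choice inbreeding avoidance supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
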