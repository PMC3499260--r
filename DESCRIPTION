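Package: admixgraph
Title: Admixture Graphs from Genome-Wide Allele Frequency Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers population splits and mixtures from genome-wide allele
    count data. Models allele frequency evolution as Gaussian drift along a
    rooted directed acyclic graph, estimates a bias-corrected centered
    covariance matrix of allele frequencies with block-resampled standard
    errors, fits branch lengths by non-negative least squares under a
    composite likelihood, searches for a maximum-likelihood population tree,
    adds weighted migration edges guided by residuals, tests edge weights by
    block jackknife, and provides three- and four-population tests of
    treeness. Includes a generative simulator so the whole pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
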