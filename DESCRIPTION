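Package: segtrends
Title: Permutation Tests for Trends in Trilobite Trunk Segmentation
Version: 0.1.0
Authors@R: person("segtrends", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing long-term trends in arthropod segment counts
    across geological time bins. Implements familywise-error-controlled
    permutation tests for pairwise location shifts in the median among multiple
    groups (single-step max-statistic and step-down conservative-maximal-subsets
    procedures), an exact enumeration oracle for small instances, distribution
    shape diagnostics, sensitivity analyses (leave-one-clade-out jackknife,
    range rarefaction, within-family range trends, enrolment-strategy subsets),
    a heavy-tailed synthetic species-table generator, and reporting helpers
    producing tidy CSV tables and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
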