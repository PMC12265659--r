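Package: ibddiff
Title: Case-Control Mapping with Identity-by-Descent Rate Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome scans for binary traits using identity-by-descent (IBD)
    segments. Computes case-case and control-control IBD sharing rates on a
    uniform genetic-map grid, forms an outlier-robust standardized rate
    difference statistic, models the statistic track as an Ornstein-Uhlenbeck
    process, and derives family-wise error rate controlling significance
    thresholds by a discrete-spacing excursion approximation or by direct
    simulation of correlated OU processes. Includes a one-sample excess-IBD
    selection scan, a randomized-phenotype confounding check, and a seedable
    synthetic IBD segment generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
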