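Package: kdiff
Title: Family-Wise Error of Multi-Range Difference-in-K Clustering Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation machinery for studying the family-wise error rate of
    the difference in Ripley's K functions test for case-control spatial
    clustering when the test is applied at many distance ranges. Generates
    case-control point patterns from a shared-parent Poisson cluster (Cox)
    process on a square window, estimates Ripley's K with the border edge
    correction, forms the difference statistic D(h) over a grid of ranges,
    evaluates it by random-labeling Monte Carlo tests (pointwise envelopes,
    simultaneous envelopes, and an integrated standardized-sum statistic),
    and aggregates many simulated datasets into family-wise error rate
    estimates with binomial confidence intervals and rejection-correlation
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
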