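Package: tonicgaba
Title: Quantification of Tonic GABA-A Currents from Whole-Cell Voltage-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify tonic (extrasynaptic GABA-A receptor mediated)
    currents from whole-cell voltage-clamp recordings of neurons. Implements
    the all-point-histogram method: event-free 5-second epochs are selected
    before and after drug application, their all-point histograms are fitted
    with Gaussians constrained to exclude the spontaneous-IPSC tail, and the
    tonic current is the difference between the fitted pre- and post-drug
    holding currents, optionally normalized by cell capacitance. Includes a
    synthetic trace generator with known ground truth (Poisson spontaneous
    IPSC arrivals, bi-exponential kernels, drug wash-in), passive membrane
    property estimation from current-step responses, exact small-sample
    Mann-Whitney U tests via the null-distribution counting recursion, a
    2^-ddCt relative-quantification helper, and a reproducible
    simulate-quantify-compare pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
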