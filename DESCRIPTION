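Package: streamsdm
Title: Riverscape Species Distribution Modelling on Synthetic Stream
    Networks
Version: 0.1.0
Authors@R: person("Riverscape", "Maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: End-to-end habitat modelling for stream-dwelling species:
    synthetic drainable terrain and monthly climate generation, D8 flow
    routing with Strahler ordering and 100 m reach characterization,
    statistical climate downscaling by geographically weighted regression
    with ordinary kriging and station correction, derivation of the 19
    bioclimatic plus 8 catchment-averaged hydroclimatic predictors, a
    from-scratch L1-regularized maximum-entropy presence-background model
    with candidate-model selection by partial ROC, omission rate and AICc,
    and present-versus-future habitat classification with change
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
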