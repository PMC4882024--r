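Package: stagepp
Title: Environmental Filtering and Dispersal Limitation Across Plant Life Stages
Version: 0.1.0
Authors@R:
    person("Ada", "Greene", email = "ada.greene@example.org",
           role = c("aut", "cre"))
Description: Spatial point-pattern analysis of mapped forest-plot censuses to
    separate the two clustering processes behind aggregated plant
    distributions: environmental filtering and dispersal limitation.
    Implements a species-habitat association test against a fitted Thomas
    (Poisson cluster) null model, a dispersal-limitation test against a
    heterogeneous Poisson null with log-linear intensity on principal
    components of topographic and edaphic surfaces, and a joint Cox process
    model with a Matern-covariance residual whose spatial variance
    decomposition yields the proportion of variance explained by environment
    (PVE) versus residual clustering (PVD = 1 - PVE). Includes quadrat
    topography and habitat classification, ordinary block kriging of soil
    variables, edge-corrected second-order summary statistics with Monte
    Carlo envelopes and the Loosmore goodness-of-fit test, a life-stage
    pipeline, and a synthetic plot generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
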