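Package: rpclust
Title: Robust Profile Clustering of Categorical Dietary Intake Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the robust profile clustering (RPC) model, a Bayesian joint
    global/local latent class model for categorical consumption data, by Gibbs
    sampling with Dirichlet-multinomial conjugacy and overfitted (sparse)
    finite mixtures.  Persons belong to one global dietary pattern shared by
    the whole population and one local pattern specific to a predefined
    subgroup; a per-person-per-item binary indicator decides whether each food
    item follows the global or the local process.  Includes preprocessing of
    averaged 24-hour dietary recalls into 4-level consumption categories
    (none / tertiles of positive consumption), study eligibility filtering,
    cardiovascular risk-factor flag derivation, a synthetic-data generator
    with known global/local structure for validation, posterior
    post-processing (occupancy-based pruning, relabeling, modal patterns,
    global-allocation heatmaps), and survey-weighted descriptive summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
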