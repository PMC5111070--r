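Package: onca
Title: Population Status Assessment and Spatial Conservation Prioritization
    for Large Carnivores
Version: 0.1.0
Authors@R:
    person("Atlantic Forest Carnivore Tools", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A reusable pipeline for assessing the population status of a
    large carnivore and prioritizing areas for its conservation. Implements
    post-processing and evaluation of continuous habitat-suitability
    surfaces (spatial thinning, threshold selection, reclassification,
    AUC/omission/binomial evaluation), delineation of occupied habitat
    fragments split by roads, Bayesian spatially explicit capture-recapture
    (SECR) density estimation with data augmentation, the Burnham-Overton
    jackknife heterogeneity (Mh) abundance estimator with a buffer-union
    effective sampled area, rule-based classification of conservation
    units, and least-cost connectivity between units. Includes a
    synthetic-data module that generates autocorrelated landscapes, roads,
    presence records and SECR capture histories with known ground truth so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
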