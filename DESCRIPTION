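Package: contourIOV
Title: Interobserver Variation Analysis for Multi-Observer Tumour Delineations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies interobserver variation (IOV) among expert
    delineations of the same anatomical target on a shared planning-CT
    voxel grid. Builds strict-majority ("median") and union consensus
    contours, computes volumetric Dice, surface Dice at a distance
    tolerance, percentile directed Hausdorff distance and mean distance
    to agreement, categorizes agreement levels, and compares observer
    groups with rank-sum tests, including pooled, subtype and exclusion
    analyses. Ships a synthetic phantom-and-observer simulator with
    controllable boundary noise, systematic volume bias and secondary
    lesion misses, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
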