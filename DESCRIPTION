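Package: memglyco
Title: Membrane-Glycopeptide Binding Analysis with Funnel-Restrained Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peptide-membrane binding simulations of
    helical glycopeptides at phospholipid bilayers. Implements the cone-plus-
    cylinder funnel restraint (boundary geometry, repulsive wall energy and
    force, exclusion of biased frames), a rational switching-function contact
    collective variable with bound-pose classification, helix-core Calpha RMSD
    pose clustering with average linkage and representative extraction, and
    per-carbon acyl-chain deuterium order parameters (S_CD) with profile
    comparison. A coarse-grained rigid-body Langevin simulator generates
    funnel-restrained trajectories with known ground truth, and bilayer
    generators produce frames with prescribed chain order, so every analysis
    stage is exercised against constructed truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
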