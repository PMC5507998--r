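Package: pbsnet
Title: Pseudo-Bootstrap Network Analysis with Random Brain Parcellations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates ensembles of roughly equal-sized random parcellations
    of a gray-matter voxel mask by farthest-point seed placement and region
    growing under a density-weighted geodesic distance, builds structural
    (streamline-count) and functional (Pearson correlation) brain networks
    for each parcellation, and treats the resulting per-parcellation network
    metrics as a pseudo-bootstrap (PBS) sample of one underlying connectome.
    Provides variance decomposition of global network metrics into
    parcellation, between-scan and between-subject components, test-retest
    intraclass correlation comparisons, and functional-connectivity
    fingerprinting of subjects across sessions from the mean-FC vector.
    Includes synthetic-data generators (cortical-shell masks, streamline
    cohorts, two-session BOLD cohorts) with controlled variance components
    so every stage can be exercised without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    RNifti,
    nortest,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
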