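Package: vascquant
Title: Quantification of Tumor Vasculature in Multi-Channel Fluorescence
    Images
Version: 0.1.0
Authors@R:
    person("Vascquant", "Developers", email = "vascquant@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the tumor vascular microenvironment in
    calibrated multi-channel immunofluorescence images: intensity-ratio
    segmentation against a local background and a negative-control floor,
    construction of total-tissue, vascular and perivascular regions of
    interest, surface- and object-based marker indices (proliferation,
    cell death, hypoxia, perfusion, endothelial junctions, pericyte
    coverage), cell-to-nearest-vessel distance profiles, skeleton-based
    vessel network metrics (microvessel density, branching, diameter,
    tortuosity), and rank-based group statistics (Mann-Whitney,
    Kruskal-Wallis with Dunn post tests).  A synthetic-scene generator
    produces calibrated images of tubular vessel networks, nuclei fields,
    pericyte shells, distance-thresholded hypoxia and perfusion markers
    with exact ground truth, so the full pipeline can be validated
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
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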