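Package: conereg
Title: Cone-Fiducial Registration of Hard-Tissue Histology Sections into MicroCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially registers 2D hard-tissue histology sections into 3D
    microCT volumes using three cone-shaped fiducial markers co-embedded with
    the specimen in resin. The cones are segmented from the CT volume and
    modelled geometrically (centroid, inertia axis, smoothed diameter-to-height
    lookup table); the elliptic cone cross-sections in the stained section are
    detected and their minor axes inverted through the lookup tables to infer
    the physical cutting plane; the matching in-silico plane is resampled from
    the volume and rigidly co-registered with the section; the match is
    quantified with Jaccard (IoU) and Dice overlap scores after frayed-edge
    exclusion. Includes a ground-truthed synthetic phantom generator so the
    whole pipeline can be validated without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    yaml,
    png,
    tiff,
    RNifti,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
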