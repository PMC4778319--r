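Package: scvtomo
Title: Simulation and Quantification of Nanoparticle-Loaded Vesicles in
    Cryo-Soft X-Ray Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the intracellular accumulation of
    superparamagnetic iron oxide nanoparticles (SPION) with cryo-soft X-ray
    tomography. Generates synthetic cell phantoms with known ground truth
    (ellipsoidal nucleus, perinuclear shell of nanoparticle-loaded vesicles),
    simulates water-window absorption tilt series under Beer-Lambert optics
    with optional Poisson photon noise, reconstructs volumes with a
    simultaneous iterative reconstruction technique (SIRT), segments
    high-absorption vesicles by adaptive thresholding and 3D connected
    components, and computes per-cell spatial statistics: equivalent-sphere
    diameters, distances to the nuclear surface, four-nearest-neighbour
    distances, accumulated vesicle volume and cell volume fraction. Volumes
    and tilt series are read and written as MRC; vesicle tables as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
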