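Package: rbreg
Title: Recursive Boundary Registration of Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-linear, cross-contrast registration of a cortical grey-white
    boundary surface to a geometrically distorted echo-planar-like volume.
    Boundary-based registration (BBR) is applied recursively to progressively
    smaller cuboid subregions of the mesh; the resulting local affine fits are
    combined on a shared control-point lattice (median aggregation plus
    neighbour smoothing) and turned into a globally continuous,
    topology-preserving piecewise-affine deformation via a consistent
    six-tetrahedra subdivision of each cuboid. Includes a synthetic
    gold-standard generator (gyrified-sphere phantoms, rendered volumes, smooth
    cubic-root-tapered displacement fields), registration quality metrics
    (displacement histograms, FWHM, average absolute distance, noise-robustness
    curves), FreeSurfer surface and NIfTI volume I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
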