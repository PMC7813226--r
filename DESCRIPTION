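Package: tomoseg
Title: Scriptable Segmentation and Meshing of Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, scriptable three-dimensional segmentation of computed
    tomography volumes: combined value and gradient thresholding with three
    gradient operator types, binary 3D morphology, a spherical-brush freeform
    painter writing integer tags into a label volume, seeded segmentation
    (region growing, graph cut, livewire boundary tracing, inter-slice contour
    interpolation), tag-based sub-volume extraction, and isosurface meshing
    with volume-preserving smoothing and quadric decimation. Includes a
    deterministic multi-phase CT phantom generator with ground-truth labels,
    TIFF-stack and raw+sidecar volume IO, and STL/PLY/OBJ mesh export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    igraph,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
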