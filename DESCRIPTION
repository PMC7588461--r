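Package: aftomo
Title: Label-Free Autofluorescence Optical Projection Tomography Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open analysis chain for label-free autofluorescence optical
    projection tomography (OPT) of pancreatic tissue: projection-domain
    preprocessing (percentile range cutting and contrast-limited adaptive
    histogram equalization), Fourier-registration estimation and correction of
    the center-of-rotation misalignment, parallel-beam filtered
    back-projection reconstruction, 3D segmentation of bright islets of
    Langerhans and of low-autofluorescence tumor regions, and islet
    size-distribution quantification with export to CSV. Includes a
    ground-truthed synthetic phantom generator and parallel-beam forward
    projector so that every stage can be validated by parameter recovery
    without access to biological specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
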