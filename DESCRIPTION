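Package: msicor
Title: Correlative Analysis of Mass Spectrometry Imaging with Label-Free
    Microscopy and Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, testable pipeline that links collagen-fibre coherence
    maps from second-harmonic-generation (SHG) microscopy and nuclei-density
    maps from H&E histology to MALDI mass spectrometry imaging (MSI) peptide
    signatures on a shared physical coordinate frame. Provides MSI datacube
    I/O (imzML and a plain-text fixture format), TIC normalisation,
    dataset-wide peak detection with maximal-interval feature extraction,
    structure-tensor coherence heatmaps with chaotic/organised
    classification, nuclei-per-unit-area heatmaps with high/low density
    classification, affine co-registration onto the MSI raster, QuPath-style
    GeoJSON annotation import, supervised per-peak ROC discrimination with
    candidate-marker selection, peptide/protein assignment by accurate-mass
    matching, PCA score images, bisecting k-means spatial segmentation, and
    a fully seeded multimodal phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    xml2,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
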