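Package: cortexmap
Title: Quantification Pipelines for Sensory-Evoked Cortical Imaging and
    Perisomatic Inhibitory Staining
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify widefield flavoprotein autofluorescence
    imaging (FAI) of mouse somatosensory cortex and confocal parvalbumin
    immunostaining, exercised end-to-end on synthetic data with known
    ground truth. Implements trial quality control (frame-deviation
    artifact rejection), trial averaging, spatial Gaussian smoothing,
    percent dF/F normalization against a pre-stimulus baseline, evoked
    response-window detection, half-maximum cortical-map segmentation
    with area measurement, temporal-phase durations, and surround
    (negative) signal extraction; a perisomatic parvalbumin density
    quantifier (disk median filtering, grouped maximum projection,
    Bernsen local adaptive thresholding, watershed-closed control image,
    seeded region growing with morphological dilation, and stained-area
    normalization by soma cross-section); von Frey withdrawal threshold
    computation; dendritic-spine density with branch-class grouping; ROI
    integrated density; and a generic labeled-cell counter. Synthetic
    generators for stimulus-locked fluorescence trials, ring-stained
    confocal stacks, and psychometric paw-withdrawal behavior provide
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
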