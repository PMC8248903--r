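Package: PaperECG
Title: Vendor-Agnostic Digitization of Scanned Paper ECG Records
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts scanned paper electrocardiogram (ECG) record images into
    calibrated voltage-time signals. The pipeline deskews the scan with a
    Hough-transform estimate from the background grid, removes the grid by
    histogram-valley thresholding, labels the trace with connected-component
    analysis and fuses fragments into row waveforms using a truncated Hausdorff
    distance, erases overlapping printed lead-label characters with
    correlation-template optical character recognition (OCR), extracts patient
    demographic text, and calibrates voltages against the leading DC pulse.
    Includes a synthetic record renderer with exhaustive ground truth for
    validation, and clinical agreement statistics (QTc, abnormality flags,
    Pearson correlation, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Visualization, Preprocessing, Electrocardiography
RoxygenNote: 7.3.3
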