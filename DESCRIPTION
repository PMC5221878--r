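Package: ctrecur
Title: Quantitative CT Features and Recurrence Modelling for Resected Lung Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reproduce a quantitative computed-tomography (CT) analysis
    of surgically resected lung adenocarcinoma: seeded attenuation-based region
    growing on a representative axial slice, extraction of ten two-dimensional
    size, attenuation, shape and histogram features (Feret diameter, perimeter,
    area, mean attenuation, circularity, aspect ratio, roundness, skewness,
    kurtosis, entropy), slice-thickness agreement analysis with intraclass
    correlation coefficients, and recurrence modelling with univariate and
    forward-conditional multivariable logistic regression, ROC/C-index and a
    Cox cross-check. A synthetic phantom generator produces nodule-bearing
    slice pairs (sharp 1-mm and smooth 5-mm reconstructions) with ground-truth
    masks, and a cohort simulator produces patient tables with the statistical
    structure the analysis assumes, so the full pipeline runs without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    png,
    pROC,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
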