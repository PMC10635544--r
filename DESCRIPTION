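Package: uvkinet
Title: Time-Course Kinetics and Network-Based Candidate Gene Prediction
    for UV-Induced Skin Photoaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for time-course expression studies of
    chronic UV irradiation (photoaging). Selects differentially expressed
    genes against a week-1 unirradiated control with an intrinsic-aging
    drift filter, clusters their log2 fold-change kinetics by K-means,
    computes gene-set overrepresentation (fold enrichment, Fisher's exact
    and chi-square tests, Benjamini-Hochberg adjustment), builds thresholded
    Pearson co-expression networks over the 0.001-0.999 grid, and
    prioritizes candidate genes by seed-gene neighborhood scoring with
    nested leave-one-out cross-validation and a permutation null. Includes
    a synthetic time-course generator with planted co-expression modules
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
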