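Package: mplcDx
Title: Quantitative Four-Marker Differential-Expression Model for
    Multiple Primary Lung Cancer versus Intrapulmonary Metastasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a quantitative immunohistochemistry-based
    diagnostic model that discriminates multiple primary lung cancer
    (MPLC) from intrapulmonary metastasis (IPM). Percent-positivity
    readings for p53, p16, p27 and c-erbB2 are averaged over five
    microscope fields, binned to decile staining scores, and the
    absolute per-marker score differences between two lesions (D-values)
    are summed; pairs whose total exceeds 90 are called MPLC, otherwise
    metastatic. The package ships the published lymph-node-metastasis
    control D-values and reclassification counts as validated fixtures,
    computes agreement statistics (percent agreement, Cohen's kappa) and
    threshold-sweep operating characteristics, and provides a seeded
    synthetic tumor-pair generator (zero-inflated Beta marker laws,
    clonal drift) for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'ihcScoring.R'
    'io.R'
    'dvalueModel.R'
    'fixtures.R'
    'concordance.R'
    'syntheticData.R'
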