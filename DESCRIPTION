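Package: strokescribe
Title: Atlas-Based Quantification and Automated Radiological Reporting of
    Acute Ischemic Stroke MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies acute ischemic infarcts from binary lesion masks in
    a common template space. Computes per-region quantitative feature
    vectors (the fraction of each parcellation region occupied by the
    infarct, plus the log lesion volume), peri-ventricular CSF-ratio
    features for hydrocephalus assessment from ADC maps, and per-region
    binary classifiers from seven model families selected by a
    cross-validated balanced-accuracy plus F1 criterion. Predictions are
    explained with additive Shapley attributions and rendered into a
    structured radiological report (hemisphere, arterial territories,
    brain structures, hydrocephalus, MCA-ASPECTS). A synthetic phantom
    module generates labeled volumes, coalescent lesions with known
    per-region overlap, ADC phantoms, and labeled cohorts, so the whole
    pipeline can be exercised without any external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    class,
    nnet,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
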