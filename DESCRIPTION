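Package: cortecm
Title: Two-Phase Outlier Rejection and Ensemble Classification for
    Tabular Clinical Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Training-set cleaning and diagnosis for labeled numeric
    tables. Implements CORT, a combined outlier rejection technique with
    a quick rejection phase (class-conditional standard-deviation
    filtering) and an accurate rejection phase (instance subset selection
    by binary Harris hawks optimization with an S-shaped transfer
    function and a k-nearest-neighbour leave-one-out fitness), preceded
    by min-max normalization and information-gain feature ranking and
    followed by a majority-vote ensemble of naive Bayes,
    k-nearest-neighbour and support-vector classifiers under stratified
    k-fold cross-validation. Ships a synthetic two-class tabular data
    generator with planted outliers and a reader/writer for the
    Wisconsin breast cancer (original) file dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
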