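Package: auface
Title: Action-Unit Tuning and Cross-Database Generalization of Facial
    Expression Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis framework for comparing facial-expression
    databases through the lens of the Facial Action Coding System (FACS).
    Twin synthetic face databases with partly shared, partly divergent
    expression-to-action-unit (AU) mappings are generated, standardized
    (histogram adjustment to mean 128 / SD 32, oval masking) and augmented;
    classifiers with a frozen convolutional backbone and a trainable
    fully connected head are trained to label seven facial expressions;
    cross-database generalization is measured with matched and swapped
    confusion matrices; the selectivity of the seven output units to 20
    action units is probed with single-AU stimulus series and summarized
    by baseline-subtracted tuning profiles, Spearman profile correlations,
    correlation-versus-confusion analysis, and principal component
    analysis of signed-extremum profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
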