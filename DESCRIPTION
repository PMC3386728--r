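Package: aromafuse
Title: Electronic-Nose and Acoustic Sensor Fusion for Fruit Maturity
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Low-level fusion of electronic-nose smellprints and acoustic
    firmness indices for classifying climacteric fruit maturity and ripeness.
    Provides fractional-response preprocessing of gas-sensor sniff traces,
    acoustic firmness indices, per-modality autoscaling and feature-level
    fusion, principal component analysis with a cumulative-variance retention
    rule, Fisher linear discriminant analysis with leave-one-out
    cross-validation and Wilks' lambda variable screening, and a competitive
    learning neural network (Kohonen rule with conscience bias learning)
    driven by the discriminant scores. A seedable synthetic-data generator
    reproduces the statistical structure of a six-class mango maturity study
    so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'chemometrics.R'
    'clnn.R'
    'preprocessing.R'
    'fusion.R'
    'io.R'
    'synthetic-data.R'
    'pipeline.R'
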