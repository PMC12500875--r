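Package: buckpi
Title: Physics-Guided Dimensionless Feature Engineering and Regression for Biofilter Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs dimensionless pi-groups from dimensional process
    variables by exact rational null-space analysis of the dimensional matrix
    (Buckingham Pi theorem), fits monomial power-law models and small
    feedforward neural networks on those features, and benchmarks them against
    purely data-driven feature reduction (PCA, kernel PCA, autoencoder) paired
    with ridge, gradient boosting, random forest and support vector regressors.
    Includes a synthetic biofilter data generator with a known monomial ground
    truth, study-based train/test splitting, standardization utilities, and an
    evaluation module (R-squared, symmetric MAPE, Pearson correlation)
    aggregating results across seeds. Aimed at effluent organic carbon
    prediction for granular activated carbon drinking-water biofilters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    kernlab,
    randomForest,
    xgboost,
    e1071
Suggests: testthat (>= 3.0.0), MASS, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
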