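Package: maizeGxEM
Title: Multimodal Genotype-by-Environment-by-Management Maize Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline for field-level maize grain-yield prediction
    from genotype, environment, and management (GxExM) data in the style of
    the Genomes to Fields (G2F) multi-environment trials. Provides a
    synthetic six-table G2F-like data generator with known injected effects;
    preprocessing with location-hierarchy imputation, weekly weather
    aggregation, and SNP call-string dosage encoding with an
    informative-locus filter; engineered state/hybrid yield features and a
    per-state linear yield trend; a multimodal convolutional neural network
    with six input branches, ELU activations, and L1-regularized dense
    layers, ensembled with a gradient-boosted model trained on oversampled
    treatment classes; LASSO, random forest, and XGBoost baselines;
    RMSE/RRMSE/MAPE/Pearson evaluation overall and per treatment; and an
    empirical rule-based tool classifying hybrid-by-treatment yield
    distributions into six performance classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
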