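test_that("default hyperparameters carry the documented values", {
  mc <- model_config()
  expect_equal(mc$lasso_penalty, 0.05)
  expect_equal(mc$rf[c("max_depth", "min_samples_split", "n_trees")],
               list(max_depth = 15, min_samples_split = 15, n_trees = 400))
  expect_equal(mc$rf$max_features, "sqrt")
  expect_equal(mc$xgb[c("max_depth", "eta", "subsample", "n_trees")],
               list(max_depth = 5, eta = 0.05, subsample = 0.75,
                    n_trees = 4000))
  expect_equal(mc$cnn$alpha, 1)
  expect_error(model_config(cnn = list(alpha = -1)))
})

test_that("treatment oversampling appends the documented counts", {
  base <- data.frame(
    treatment = rep(c("standard", "drought", "irrigated", "disease trial",
                      "late stressed", "dryland"), each = 10),
    yield = rnorm(60))
  out <- oversample_treatments(base, per_treatment = 4000, late_relabel = 1000,
                               seed = 1)
  expect_equal(nrow(out) - nrow(base), 25000)
  expect_equal(sum(out$treatment == "late planting" & out$oversampled), 5000)
  # originals untouched, in place, flagged FALSE
  expect_identical(out$yield[1:60], base$yield)
  expect_false(any(out$oversampled[1:60]))

  # no eligible treatments -> warning and zero appended
  solo <- data.frame(treatment = rep("standard", 5), yield = 1:5)
  expect_warning(out2 <- oversample_treatments(solo), "no eligible")
  expect_equal(nrow(out2), 5)

  # small worked example
  d <- data.frame(treatment = c(rep("drought", 4), "standard"), yield = 1:5)
  out3 <- oversample_treatments(d, per_treatment = 10, late_relabel = 2,
                                seed = 2)
  expect_equal(nrow(out3) - nrow(d), 12)
  expect_equal(sum(out3$treatment == "late planting"), 2)
})

test_that("appended-count formula holds for random eligible sets", {
  pool <- c("standard", "late planting", "drought", "irrigated",
            "disease trial", "early planting", "late stressed", "dryland")
  withr::with_seed(51, {
    for (rep in 1:10) {
      labs <- sample(pool, sample(1:8, 1))
      rows <- data.frame(treatment = rep(labs, each = 3), yield = 0)
      n_elig <- length(setdiff(labs, c("standard", "late planting")))
      pt <- sample(5:20, 1); lr <- sample(1:5, 1)
      out <- suppressWarnings(
        oversample_treatments(rows, per_treatment = pt, late_relabel = lr,
                              seed = rep))
      expect_equal(nrow(out) - nrow(rows), n_elig * (pt + lr))
    }
  })
})

test_that("ensemble weighting is exact arithmetic and preserves constants", {
  w <- list(w_xgb = 0.1, w_cnn = 0.9)
  expect_equal(ensemble_predict(w, 20, 10), 11.0)
  p <- rnorm(10)
  for (wx in seq(0, 1, 0.1))
    expect_equal(ensemble_predict(list(w_xgb = wx, w_cnn = 1 - wx), p, p), p)
  expect_error(ensemble_predict(w, 1:3, 1:2), "length")
  expect_error(ensemble_predict(list(w_xgb = 0.5, w_cnn = 0.6), 1, 1), "sum")
})

test_that("weight grid search equals an exhaustive scan and finds oracles", {
  withr::with_seed(52, {
    y <- runif(50, 5, 12)
    p_cnn <- y + rnorm(50, 0, 0.5)
    p_xgb <- y + rnorm(50, 0, 1.5)
    w <- grid_search_ensemble_weights(p_xgb, p_cnn, y)
    # brute-force oracle over the 11 weight pairs
    errs <- sapply(seq(0, 1, 0.1), function(wx)
      rmse(y, wx * p_xgb + (1 - wx) * p_cnn))
    expect_equal(w$rmse, min(errs))
    expect_equal(w$w_xgb, seq(0, 1, 0.1)[which.min(errs)])
    expect_equal(w$w_xgb + w$w_cnn, 1)
    # perfect CNN predictions force w_cnn = 1
    w2 <- grid_search_ensemble_weights(rnorm(50), y, y)
    expect_equal(w2$w_cnn, 1)
    # ties resolve toward the CNN
    w3 <- grid_search_ensemble_weights(y, y, y)
    expect_equal(w3$w_cnn, 1)
  })
  expect_error(grid_search_ensemble_weights(1:3, 1:2, 1:3), "equal length")
})

test_that("yield-feature design matrix excludes the high-dimensional blocks", {
  fx <- make_model_fixture()
  X <- yield_feature_matrix(fx$tr$frame,
                            list(state = "ST1", treatment = "standard"))
  expect_equal(ncol(X), length(YIELD_FEATURE_COLS) + 2)
  expect_false(any(grepl("soil|L[0-9]", colnames(X))))
  bad <- fx$tr$frame[, setdiff(names(fx$tr$frame), "sh_mean")]
  expect_error(yield_feature_matrix(bad, list(state = "a", treatment = "b")),
               "missing yield-feature")
})

test_that("yield-feature XGBoost is seed-reproducible and learns sh-mean signal", {
  # yields driven purely by the state-hybrid mean: high test correlation
  es <- synthetic_config()$effect_sizes
  es$noise_sd <- 0.3
  es$planting_penalty <- 0
  es$treatment_offsets[] <- 0
  raw <- generate_dataset(synthetic_config(seed = 21, effect_sizes = es))
  prep <- preprocess_dataset(raw, locus_filter_params(n_sample = 20, seed = 2))
  fr <- prep$merged$frame
  is_train <- fr$year <= 2020
  aug <- add_yield_features(fr, fr[is_train, c("state", "hybrid", "year",
                                               "yield")])
  cat_levels <- list(state = sort(unique(aug$state)),
                     treatment = sort(unique(aug$treatment)))
  m1 <- train_xgb_yield_features(aug[is_train, ], cat_levels,
                                 nrounds = 300, seed = 4)
  m2 <- train_xgb_yield_features(aug[is_train, ], cat_levels,
                                 nrounds = 300, seed = 4)
  p1 <- predict(m1, aug[!is_train, ])
  expect_identical(p1, predict(m2, aug[!is_train, ]))
  expect_gt(pearson(fr$yield[!is_train], p1), 0.9)
})

test_that("baseline models train on the flat matrix and beat the mean", {
  fx <- make_model_fixture()
  base <- const_rmse(fx$te$y, fx$tr$y)
  for (nm in c("lasso", "rf", "xgb")) {
    m <- fit_baseline(nm, fx$tr$flat, fx$tr$y, seed = 1, nrounds = 200)
    r <- rmse(fx$te$y, predict(m, fx$te$flat))
    expect_lt(r, base)
  }
  expect_error(fit_baseline("gbm", fx$tr$flat, fx$tr$y), "arg")
})

test_that("single-modal network fits a 200-row training set better than the mean", {
  withr::with_seed(53, {
    n <- 200; p <- 60
    X <- matrix(rnorm(n * p), n)
    y <- 9 + 1.5 * X[, 1] - X[, 5] + 0.5 * X[, 10] + rnorm(n, 0, 0.3)
    mc <- test_cnn_config(epochs = 40)
    net <- build_single_modal(p, mc)
    fit <- fit_cnn_dnn(net, list(x = X), y, mc)
    train_rmse <- rmse(y, predict(fit, list(x = X)))
    expect_lt(train_rmse, rmse(y, rep(mean(y), n)))
  })
})

test_that("CNN-DNN training is reproducible for a fixed seed", {
  withr::with_seed(54, {
    X <- matrix(rnorm(60 * 30), 60)
    y <- rnorm(60)
  })
  mc <- test_cnn_config(epochs = 3, seed = 9)
  f1 <- fit_cnn_dnn(build_single_modal(30, mc), list(x = X), y, mc)
  f2 <- fit_cnn_dnn(build_single_modal(30, mc), list(x = X), y, mc)
  expect_identical(predict(f1, list(x = X)), predict(f2, list(x = X)))
})

test_that("multimodal network validates block shapes and sample counts", {
  fx <- make_model_fixture()
  mc <- test_cnn_config(epochs = 1)
  net <- build_multimodal(multimodal_shapes(fx$tr), mc)
  expect_length(net$branch_groups$envsim_soil, 7)
  expect_equal(net$input_shapes$weather, c(48, 16, 1))
  out <- nn_forward(net, lapply(fx$tr$inputs, slice_input, idx = 1:5))
  expect_equal(dim(out), c(5, 1))
})
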