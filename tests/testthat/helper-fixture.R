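# Shared fixtures, built once per test run. Sizes are desk-scale: a 3-state
# cohort for fast unit tests and a 5-state cohort (300-row training
# subsample) for the model-quality tests.

tiny_synth_config <- function(seed = 42L, ...) {
  synthetic_config(n_states = 3, envs_per_state = 1, years = 2018:2021,
                   n_hybrids = 24, n_loci = 200, seed = seed, ...)
}

# small preprocessed fixture: merged frame + selected loci
make_tiny_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      raw <- generate_dataset(tiny_synth_config())
      cache <<- list(
        raw = raw,
        prep = preprocess_dataset(raw, locus_filter_params(n_sample = 15,
                                                           seed = 2)))
    }
    cache
  }
})

# model-scale fixture: 300 training rows, full 2021 test split, with
# engineered features and prepared input blocks
make_model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      raw <- generate_dataset(synthetic_config(seed = 7))
      prep <- preprocess_dataset(raw, locus_filter_params(n_sample = 40,
                                                          seed = 3))
      fr <- prep$merged$frame
      is_train <- fr$year <= 2020
      training <- fr[is_train, c("state", "hybrid", "year", "yield")]
      aug <- add_yield_features(fr, training)
      m <- prep$merged
      m$frame <- aug
      sub <- function(idx) list(frame = m$frame[idx, , drop = FALSE],
                                weather = m$weather[idx, , , drop = FALSE],
                                genotype = m$genotype[idx, , drop = FALSE])
      tr_idx <- withr::with_seed(5, sort(sample(which(is_train), 300)))
      tr <- prepare_model_data(sub(tr_idx), prep$loci)
      te <- prepare_model_data(sub(which(!is_train)), prep$loci,
                               template = tr)
      cache <<- list(raw = raw, prep = prep, tr = tr, te = te,
                     training = training)
    }
    cache
  }
})

# small CNN settings used throughout the tests (documented problem size)
test_cnn_config <- function(epochs = 25, seed = 2L, ...) {
  model_config(cnn = c(list(epochs = epochs, seed = seed, filters1 = 8L,
                            filters2 = 4L, dense_units = c(32L, 8L),
                            batch_size = 32), list(...)))
}

const_rmse <- function(y_test, y_train) rmse(y_test, rep(mean(y_train), length(y_test)))
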