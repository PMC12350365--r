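# Model families: LASSO / random forest / XGBoost baselines on the flat
# feature matrix, the single-modal CNN-DNN on the same flat input, the
# multimodal CNN-DNN with six input branches, the oversampled
# yield-feature XGBoost, and the weighted ensemble of the last two.

ENVSIM_GROUPS_10x9 <- c("SWSD", "ESW", "FlowUp", "NO3Leach", "SWC", "PAW")
ENVSIM_GROUP_9x9 <- "Flow"

#' Default model hyperparameters
#'
#' Baseline defaults: LASSO L1 penalty 0.05; random forest depth 15,
#' sqrt(p) features per split, minimum node size 15, 400 trees; XGBoost
#' depth 5, eta 0.05, subsample 0.75, 4000 trees. CNN defaults: ELU alpha 1,
#' L1 1e-4 on the final dense layers, learning rate 0.01.
#'
#' @param cnn Overrides for the CNN settings (epochs, batch_size, lr, seed,
#'   alpha, l1, filters).
#' @return Nested list of class `model_config`.
#' @export
model_config <- function(cnn = list()) {
  cnn_defaults <- list(alpha = 1, l1 = 1e-4, lr = 0.01, epochs = 60,
                       batch_size = 32, seed = 1L,
                       filters1 = 32L, filters2 = 16L, kernel = 5L,
                       pool = 2L, dense_units = c(64L, 16L))
  cnn_defaults[names(cnn)] <- cnn
  stopifnot(cnn_defaults$alpha > 0, cnn_defaults$l1 >= 0, cnn_defaults$lr > 0)
  structure(list(
    lasso_penalty = 0.05,
    rf = list(max_depth = 15, max_features = "sqrt", min_samples_split = 15,
              n_trees = 400),
    xgb = list(max_depth = 5, eta = 0.05, subsample = 0.75, n_trees = 4000),
    cnn = cnn_defaults
  ), class = "model_config")
}

# embedding width rule: min(8, ceil(cardinality / 2))
embed_dim_for <- function(cardinality) pmin(8L, as.integer(ceiling(cardinality / 2)))

#' Prepare model inputs from a merged frame
#'
#' Splits a [join_all()] result (already augmented with
#' [add_yield_features()] columns) into the six shaped blocks the multimodal
#' network consumes, plus the flat matrix used by baselines and the
#' single-modal network. Rows flagged `genotype_missing` are dropped.
#' Categorical metadata (state, treatment) is integer-coded against levels
#' fixed here; pass the training `prep` via `template` to code test data
#' identically.
#'
#' @param merged A `merged_frame` whose `frame` carries the engineered
#'   yield-feature columns.
#' @param loci Character vector of selected locus labels.
#' @param template Optional `model_data` from the training split supplying
#'   categorical level sets.
#' @return List of class `model_data`: `inputs` (named blocks), `flat`
#'   (n x p matrix), `y`, `frame`, `cat_levels`.
#' @export
prepare_model_data <- function(merged, loci, template = NULL) {
  keep <- !merged$frame$genotype_missing
  fr <- merged$frame[keep, , drop = FALSE]
  weather <- merged$weather[keep, , , drop = FALSE]
  geno <- merged$genotype[keep, loci, drop = FALSE]
  n <- nrow(fr)

  cat_levels <- if (!is.null(template)) template$cat_levels else
    list(state = sort(unique(fr$state)),
         treatment = sort(unique(fr$treatment)))
  code <- function(v, lev) {
    i <- match(v, lev)
    i[is.na(i)] <- length(lev) + 1L  # unseen level -> shared "other" slot
    i
  }
  cat_mat <- cbind(state = code(fr$state, cat_levels$state),
                   treatment = code(fr$treatment, cat_levels$treatment))

  num_cols <- c("planting_doy", "sh_mean", "sh_max", "sh_min", "h_mean",
                "h_max", "h_min", "parent1_mean", "parent2_mean", "trend")
  num_cols <- intersect(num_cols, names(fr))
  num_mat <- as.matrix(fr[, num_cols, drop = FALSE])

  soil_cols <- grep("^soil_", names(fr), value = TRUE)
  soil <- as.matrix(fr[, soil_cols, drop = FALSE])

  env_block <- function(g, d) {
    cols <- paste0(g, "_d", rep(seq_len(d), times = 9),
                   "_s", rep(1:9, each = d))
    arr <- array(as.matrix(fr[, cols, drop = FALSE]), c(n, d, 9, 1))
    arr
  }
  envsim <- lapply(ENVSIM_GROUPS_10x9, env_block, d = 10)
  names(envsim) <- paste0("envsim_", ENVSIM_GROUPS_10x9)
  envsim[[paste0("envsim_", ENVSIM_GROUP_9x9)]] <- env_block(ENVSIM_GROUP_9x9, 9)
  pheno_cols <- grep("^(GrainSim|Biomass|WaterTable|LAI)_s[0-9]$", names(fr),
                     value = TRUE)
  pheno <- as.matrix(fr[, pheno_cols, drop = FALSE])

  inputs <- c(list(
    weather = array(weather, c(n, dim(weather)[2], dim(weather)[3], 1)),
    soil = array(soil, c(n, ncol(soil), 1)),
    genotype = array(geno, c(n, ncol(geno), 1)),
    metadata = list(cat = cat_mat, num = num_mat)
  ), envsim, list(envsim_pheno = array(pheno, c(n, ncol(pheno), 1))))

  flat <- cbind(matrix(weather, n, prod(dim(weather)[-1])), soil, geno,
                do.call(cbind, lapply(envsim, function(a) matrix(a, n))),
                pheno, num_mat, cat_mat)
  colnames(flat) <- NULL
  structure(list(inputs = inputs, flat = flat, y = fr$yield, frame = fr,
                 cat_levels = cat_levels),
            class = "model_data")
}

#' Input shapes of a prepared model-data object
#'
#' @param md A [prepare_model_data()] result.
#' @return Named list of per-block shapes suitable for [build_multimodal()].
#' @export
multimodal_shapes <- function(md) {
  shp <- lapply(md$inputs, function(x) {
    if (is.list(x) && !is.data.frame(x)) NULL else dim(x)[-1]
  })
  shp$metadata <- list(
    cat_levels = vapply(md$cat_levels, length, integer(1)),
    num = ncol(md$inputs$metadata$num))
  shp
}

# ---- CNN-DNN architectures --------------------------------------------------

#' Build the single-modal CNN-DNN
#'
#' All inputs concatenated into one flat vector per row: input ->
#' conv1d(32, k5) -> conv1d(16, k5) -> average pooling -> two further 1D
#' conv layers -> flatten -> three dense layers ending in a scalar output.
#' ELU activations everywhere except the linear output.
#'
#' @param input_width Flat feature count per row.
#' @param config A [model_config()].
#' @return An untrained network (class `nn_net`).
#' @export
build_single_modal <- function(input_width, config = model_config()) {
  cc <- config$cnn
  if (input_width < cc$kernel)
    stop("input width ", input_width, " smaller than kernel span ", cc$kernel)
  layers <- list(
    layer_conv1d(cc$filters1, cc$kernel),
    layer_conv1d(cc$filters2, cc$kernel),
    layer_avgpool1d(cc$pool),
    layer_conv1d(cc$filters2, 3L),
    layer_conv1d(max(4L, cc$filters2 %/% 2L), 3L),
    layer_flatten(),
    layer_dense(cc$dense_units[1]),
    layer_dense(cc$dense_units[2]),
    layer_dense(1L, activation = "linear")
  )
  net <- build_nn(branches = list(x = layers),
                  input_shapes = list(x = c(input_width, 1L)),
                  head = list(), alpha = cc$alpha, seed = cc$seed)
  net$kind <- "single_modal"
  net
}

#' Build the multimodal CNN-DNN
#'
#' Six input branches: weather (n x 48 x 16, two 2D convolutions, average
#' pooling, flatten, dense), soil and genotype (1D convolution blocks),
#' metadata (two embedding layers for the categoricals concatenated with the
#' numeric columns, then two 1D convolutions and a flatten), environmental
#' soil (7 parallel 2D-convolution sub-blocks over the 10x9 depth-by-stage
#' grids and the 9x9 Flow grid, concatenated), and environmental phenology
#' (1D convolution block). Branch outputs are concatenated and passed
#' through two L1-regularized dense layers before the linear output. ELU
#' activation throughout.
#'
#' @param shapes Named list of input shapes (excluding n):
#'   `weather` c(48, 16, 1), `soil` c(S, 1), `genotype` c(L, 1),
#'   `metadata` list(cat_levels =, num =), `envsim_*` c(10, 9, 1) / c(9, 9, 1),
#'   `envsim_pheno` c(P, 1).
#' @param config A [model_config()].
#' @return Untrained `nn_net` with a `branch_groups` field naming the 7
#'   environmental-soil sub-blocks.
#' @export
build_multimodal <- function(shapes, config = model_config()) {
  cc <- config$cnn
  conv1d_block <- function(dense_out = 16L) list(
    layer_conv1d(cc$filters1, min(cc$kernel, 5L)),
    layer_conv1d(cc$filters2, 3L),
    layer_avgpool1d(cc$pool),
    layer_flatten(),
    layer_dense(dense_out)
  )
  conv2d_block <- function(k1, dense_out, f1 = cc$filters1, f2 = cc$filters2) list(
    layer_conv2d(f1, k1),
    layer_conv2d(f2, c(3L, 3L)),
    layer_avgpool2d(cc$pool),
    layer_flatten(),
    layer_dense(dense_out)
  )
  md <- shapes$metadata
  embed_dims <- embed_dim_for(md$cat_levels)
  meta_width <- sum(embed_dims) + md$num
  branches <- c(
    list(
      weather = conv2d_block(c(5L, 5L), 16L),
      soil = conv1d_block(16L),
      genotype = conv1d_block(16L),
      metadata = list(
        layer_embedding_concat(md$cat_levels + 1L, embed_dims),  # +1: unseen slot
        layer_conv1d(cc$filters2, min(3L, meta_width)),
        layer_conv1d(max(4L, cc$filters2 %/% 2L), 3L),
        layer_flatten()
      )
    ),
    stats::setNames(
      lapply(names(shapes)[grep("^envsim_(?!pheno)", names(shapes), perl = TRUE)],
             function(nm) conv2d_block(c(3L, 3L), 8L, f1 = 16L, f2 = 8L)),
      names(shapes)[grep("^envsim_(?!pheno)", names(shapes), perl = TRUE)]),
    list(envsim_pheno = conv1d_block(8L))
  )
  input_shapes <- shapes
  input_shapes$metadata <- list(num = md$num)
  head <- list(
    layer_dense(cc$dense_units[1], l1 = cc$l1),
    layer_dense(cc$dense_units[2], l1 = cc$l1),
    layer_dense(1L, activation = "linear")
  )
  net <- build_nn(branches = branches, input_shapes = input_shapes[names(branches)],
                  head = head, alpha = cc$alpha, seed = cc$seed)
  net$kind <- "multimodal"
  net$branch_groups <- list(
    envsim_soil = grep("^envsim_(?!pheno)", names(branches), perl = TRUE,
                       value = TRUE))
  net
}

# per-block standardization; metadata numerics per column, others global
make_scaler <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    mu <- colMeans(x$num); sd <- apply(x$num, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(kind = "meta", mu = mu, sd = sd)
  } else {
    mu <- mean(x); sd <- stats::sd(as.numeric(x))
    if (sd == 0 || !is.finite(sd)) sd <- 1
    list(kind = "global", mu = mu, sd = sd)
  }
}
apply_scaler <- function(x, sc) {
  if (sc$kind == "meta") {
    x$num <- sweep(sweep(x$num, 2, sc$mu), 2, sc$sd, `/`)
    x
  } else (x - sc$mu) / sc$sd
}

#' Train a CNN-DNN model
#'
#' Standardizes every input block and the response using training statistics,
#' then runs minibatch Adam on the MSE loss (plus any L1 dense penalties in
#' the architecture).
#'
#' @param net An untrained network from [build_single_modal()] or
#'   [build_multimodal()].
#' @param inputs Named list of input blocks (for the single-modal network,
#'   `list(x = flat_matrix)`); matrices are reshaped to (n, p, 1) as needed.
#' @param y Training yields (Mg/ha).
#' @param config A [model_config()]; `config$cnn` supplies epochs, batch
#'   size, learning rate, and seed.
#' @return Fitted model of class `cnn_dnn` (network + scalers).
#' @export
fit_cnn_dnn <- function(net, inputs, y, config = model_config()) {
  cc <- config$cnn
  inputs <- lapply(inputs, as_block_array)
  scalers <- lapply(inputs, make_scaler)
  xs <- mapply(apply_scaler, inputs, scalers, SIMPLIFY = FALSE)
  y_mu <- mean(y); y_sd <- stats::sd(y); if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  net <- nn_train(net, xs, (y - y_mu) / y_sd, epochs = cc$epochs,
                  batch_size = cc$batch_size, lr = cc$lr, seed = cc$seed)
  structure(list(net = net, scalers = scalers, y_mu = y_mu, y_sd = y_sd,
                 config = config),
            class = "cnn_dnn")
}

as_block_array <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1)) else x
}

#' @export
predict.cnn_dnn <- function(object, newdata, ...) {
  newdata <- lapply(newdata, as_block_array)
  xs <- mapply(apply_scaler, newdata[names(object$scalers)], object$scalers,
               SIMPLIFY = FALSE)
  as.numeric(nn_forward(object$net, xs)) * object$y_sd + object$y_mu
}

# ---- oversampling -----------------------------------------------------------

#' Oversample minority treatment classes
#'
#' For every observed treatment except the standard and late-planting
#' labels, appends `per_treatment` rows resampled with replacement, plus
#' `late_relabel` resampled rows whose treatment is renamed to the
#' late-planting label (the training data holds no real late-planting rows).
#' Original rows are untouched; with five eligible treatments and the
#' defaults this appends 5 x (4000 + 1000) = 25,000 rows.
#'
#' @param rows Training data.frame with a `treatment` column.
#' @param per_treatment Resamples per eligible treatment (default 4000).
#' @param late_relabel Relabeled resamples per eligible treatment (default
#'   1000).
#' @param seed Integer seed.
#' @param standard_label,late_label Labels excluded from the eligible set.
#' @return `rows` plus appended resamples, with a logical `oversampled`
#'   column.
#' @export
oversample_treatments <- function(rows, per_treatment = 4000L,
                                  late_relabel = 1000L, seed = 1L,
                                  standard_label = "standard",
                                  late_label = "late planting") {
  eligible <- setdiff(unique(rows$treatment), c(standard_label, late_label))
  rows$oversampled <- FALSE
  if (length(eligible) == 0) {
    warning("no eligible treatments to oversample")
    return(rows)
  }
  with_seed(seed, {
    app <- lapply(eligible, function(tr) {
      pool <- which(rows$treatment == tr)
      a <- rows[sample(pool, per_treatment, replace = TRUE), , drop = FALSE]
      b <- rows[sample(pool, late_relabel, replace = TRUE), , drop = FALSE]
      b$treatment <- late_label
      rbind(a, b)
    })
    out <- rbind(rows, do.call(rbind, app))
  })
  out$oversampled <- c(rep(FALSE, nrow(rows)),
                       rep(TRUE, nrow(out) - nrow(rows)))
  rownames(out) <- NULL
  out
}

# ---- yield-feature XGBoost --------------------------------------------------

YIELD_FEATURE_COLS <- c("planting_doy", "sh_mean", "sh_max", "sh_min",
                        "h_mean", "h_max", "h_min", "parent1_mean",
                        "parent2_mean", "trend")

# metadata + yield-feature design matrix (no weather/soil/genotype/envsim)
yield_feature_matrix <- function(rows, cat_levels) {
  miss <- setdiff(YIELD_FEATURE_COLS, names(rows))
  if (length(miss) > 0)
    stop("missing yield-feature columns: ", paste(miss, collapse = ", "))
  code <- function(v, lev) { i <- match(v, lev); i[is.na(i)] <- length(lev) + 1L; i }
  cbind(as.matrix(rows[, YIELD_FEATURE_COLS, drop = FALSE]),
        state = code(rows$state, cat_levels$state),
        treatment = code(rows$treatment, cat_levels$treatment))
}

#' XGBoost on metadata and yield features only
#'
#' Gradient-boosted regressor restricted to metadata (state, treatment,
#' planting day) and the engineered hybrid-level and state-hybrid-level
#' yield features; trained on the oversampled rows. Deterministic for a
#' given seed (single thread, exact tree method).
#'
#' @param rows Oversampled training rows carrying the yield-feature columns.
#' @param cat_levels List with `state` and `treatment` level vectors.
#' @param config A [model_config()] (uses `config$xgb`).
#' @param nrounds Boosting rounds; defaults to `config$xgb$n_trees`.
#' @param seed Integer seed.
#' @return Object of class `xgb_yield_features`.
#' @export
train_xgb_yield_features <- function(rows, cat_levels, config = model_config(),
                                     nrounds = NULL, seed = 1L) {
  X <- yield_feature_matrix(rows, cat_levels)
  px <- config$xgb
  booster <- xgboost::xgb.train(
    data = xgboost::xgb.DMatrix(X, label = rows$yield, nthread = 1),
    nrounds = nrounds %||% px$n_trees,
    params = list(max_depth = px$max_depth, eta = px$eta,
                  subsample = px$subsample, tree_method = "exact",
                  nthread = 1, seed = seed, objective = "reg:squarederror"),
    verbose = 0)
  structure(list(booster = booster, cat_levels = cat_levels),
            class = "xgb_yield_features")
}

#' @export
predict.xgb_yield_features <- function(object, newdata, ...) {
  X <- yield_feature_matrix(newdata, object$cat_levels)
  stats::predict(object$booster, X)
}

# ---- baselines --------------------------------------------------------------

#' Fit a baseline regressor on the flat feature matrix
#'
#' `lasso`: glmnet with the fixed L1 penalty; `rf`: ranger with depth 15,
#' sqrt(p) candidate features, node size 15 (closest control to a
#' minimum-samples-to-split of 15), 400 trees; `xgb`: xgboost with depth 5,
#' eta 0.05, subsample 0.75, 4000 trees.
#'
#' @param name One of "lasso", "rf", "xgb".
#' @param X Numeric feature matrix.
#' @param y Yields.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param nrounds Optional override of the XGBoost round count.
#' @return Object of class `baseline_model`.
#' @export
fit_baseline <- function(name = c("lasso", "rf", "xgb"), X, y,
                         config = model_config(), seed = 1L, nrounds = NULL) {
  name <- match.arg(name)
  fit <- switch(
    name,
    lasso = {
      sc <- list(mu = colMeans(X), sd = pmax(apply(X, 2, stats::sd), 1e-12))
      Xs <- sweep(sweep(X, 2, sc$mu), 2, sc$sd, `/`)
      list(model = glmnet::glmnet(Xs, y, alpha = 1,
                                  lambda = config$lasso_penalty,
                                  standardize = FALSE),
           scaler = sc)
    },
    rf = {
      p <- config$rf
      list(model = ranger::ranger(
        x = as.data.frame(X), y = y, num.trees = p$n_trees,
        mtry = max(1L, floor(sqrt(ncol(X)))), min.node.size = p$min_samples_split,
        max.depth = p$max_depth, seed = seed, num.threads = 1))
    },
    xgb = {
      p <- config$xgb
      list(model = xgboost::xgb.train(
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = nrounds %||% p$n_trees,
        params = list(max_depth = p$max_depth, eta = p$eta,
                      subsample = p$subsample, tree_method = "exact",
                      nthread = 1, seed = seed,
                      objective = "reg:squarederror"),
        verbose = 0))
    })
  structure(c(fit, list(name = name)), class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  switch(object$name,
         lasso = {
           Xs <- sweep(sweep(newdata, 2, object$scaler$mu), 2,
                       object$scaler$sd, `/`)
           as.numeric(stats::predict(object$model, Xs))
         },
         rf = stats::predict(object$model,
                             data = as.data.frame(newdata))$predictions,
         xgb = stats::predict(object$model, newdata))
}

# ---- ensemble ---------------------------------------------------------------

#' Grid search over ensemble weights
#'
#' Scans w_xgb over \{0, step, ..., 1\} with w_cnn = 1 - w_xgb and returns
#' the pair minimizing validation RMSE; ties resolve to the larger CNN
#' weight.
#'
#' @param pred_xgb,pred_cnn Validation predictions from the two models.
#' @param y_val Validation yields.
#' @param step Grid increment (default 0.1).
#' @return List `ensemble_weights`: `w_xgb`, `w_cnn`, `rmse`.
#' @export
grid_search_ensemble_weights <- function(pred_xgb, pred_cnn, y_val,
                                         step = 0.1) {
  if (length(pred_xgb) != length(pred_cnn) ||
      length(pred_xgb) != length(y_val))
    stop("prediction and validation vectors must have equal length")
  ws <- seq(0, 1, by = step)
  errs <- vapply(ws, function(w)
    rmse(y_val, ensemble_predict(list(w_xgb = w, w_cnn = 1 - w),
                                 pred_xgb, pred_cnn)), numeric(1))
  # first index = smallest w_xgb = largest w_cnn on ties
  best <- which(errs == min(errs))[1]
  structure(list(w_xgb = ws[best], w_cnn = 1 - ws[best], rmse = errs[best]),
            class = "ensemble_weights")
}

#' Weighted ensemble prediction
#'
#' @param w List with `w_xgb` and `w_cnn` (must sum to 1).
#' @param pred_xgb,pred_cnn Prediction vectors.
#' @return w_xgb * pred_xgb + w_cnn * pred_cnn.
#' @export
ensemble_predict <- function(w, pred_xgb, pred_cnn) {
  if (length(pred_xgb) != length(pred_cnn)) stop("length mismatch")
  if (abs(w$w_xgb + w$w_cnn - 1) > 1e-8) stop("weights must sum to 1")
  w$w_xgb * pred_xgb + w$w_cnn * pred_cnn
}
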