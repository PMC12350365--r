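# End-to-end orchestration: simulate (or load) -> preprocess -> engineer
# features -> train -> evaluate -> classify, with a strict year-based split
# and a manifest of seeds. Every stage writes its artifacts into the run
# directory so intermediate tables can be inspected.

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()] used to simulate data, or NULL
#'   when `data_dir` points at six CSV tables written by
#'   [write_dataset_csv()].
#' @param data_dir Directory with trait/metadata/weather/soil/envsim/genotype
#'   CSVs (ignored when `synthetic` is given).
#' @param train_cutoff Last training year (inclusive, default 2020).
#' @param test_year Held-out test year (default 2021); must exceed
#'   `train_cutoff`.
#' @param models Models to train: subset of "lasso", "rf", "xgb", "cnn",
#'   "multimodal", "ensemble".
#' @param model_cfg A [model_config()].
#' @param locus_params A [locus_filter_params()].
#' @param xgb_nrounds Optional reduced boosting rounds for the tree models.
#' @param oversample Apply treatment oversampling before the yield-feature
#'   XGBoost (default TRUE).
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Run directory (created).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), data_dir = NULL,
                            train_cutoff = 2020L, test_year = 2021L,
                            models = c("lasso", "rf", "xgb", "cnn",
                                       "multimodal", "ensemble"),
                            model_cfg = model_config(),
                            locus_params = locus_filter_params(),
                            xgb_nrounds = NULL, oversample = TRUE,
                            seed = 1L, out_dir = tempfile("gxem_run_")) {
  if (train_cutoff >= test_year)
    stop("validation error: train_cutoff must be below test_year")
  known <- c("lasso", "rf", "xgb", "cnn", "multimodal", "ensemble")
  if (!all(models %in% known))
    stop("unknown model(s): ", paste(setdiff(models, known), collapse = ", "))
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 train_cutoff = as.integer(train_cutoff),
                 test_year = as.integer(test_year), models = models,
                 model_cfg = model_cfg, locus_params = locus_params,
                 xgb_nrounds = xgb_nrounds, oversample = oversample,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a six-table dataset from CSV
#'
#' Inverse of [write_dataset_csv()] (truth record not recoverable).
#'
#' @param dir Directory holding the CSVs.
#' @return List resembling a `raw_dataset` (without `truth`).
#' @export
read_dataset_csv <- function(dir) {
  rd <- function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                     check.names = FALSE)
  gdf <- rd("genotype")
  calls <- as.matrix(gdf[, -1, drop = FALSE])
  rownames(calls) <- gdf[[1]]
  list(trait = rd("trait"), metadata = rd("metadata"), weather = rd("weather"),
       soil = rd("soil"), envsim = rd("envsim"), genotype_calls = calls)
}

# preprocess a raw dataset into a merged frame + selected loci
preprocess_dataset <- function(raw, locus_params, missing_marker = "./.") {
  metadata <- impute_metadata(raw$metadata)
  metadata$planting_doy <- planting_date_to_doy(metadata$planting_date)
  if ("comment" %in% names(metadata))
    metadata$issue_class <- classify_issues(metadata$comment)
  weekly <- weather_to_weekly(raw$weather)
  soil_cols <- grep("^soil_", names(raw$soil), value = TRUE)
  soil <- impute_by_location_hierarchy(raw$soil, soil_cols)
  env_cols <- setdiff(names(raw$envsim), c("env", "location", "state", "year"))
  envsim <- impute_by_location_hierarchy(raw$envsim, env_cols)

  dosages <- encode_calls(raw$genotype_calls, missing_markers = missing_marker)
  dosages <- drop_missing_loci(dosages)
  kept <- select_informative_loci(dosages, locus_params)
  if (length(kept) == 0) stop("no informative loci; relax the filter")
  loci <- sample_loci(kept, locus_params$n_sample, locus_params$seed)

  md_cols <- c("env", "treatment", "planting_doy",
               intersect("issue_class", names(metadata)))
  soil_keep <- soil[, c("env", soil_cols)]
  env_keep <- envsim[, c("env", "location", "state", "year", env_cols)]
  merged <- join_all(raw$trait, metadata[, md_cols], weekly, soil_keep,
                     env_keep, dosages)
  list(merged = merged, loci = loci, metadata = metadata,
       locus_report = attr(dosages, "removed"))
}

#' Run the full pipeline
#'
#' Simulates or loads the six tables, preprocesses and joins them, engineers
#' yield features from training years only, trains the requested models,
#' evaluates them on the held-out year, classifies hybrids, and writes all
#' artifacts plus a manifest into the run directory. The temporal split is
#' strict: no test-year row enters any feature statistic, imputation, or fit.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path (invisibly, with the result list as
#'   attribute `result`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  raw <- stage("simulate", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      generate_dataset(cfg)
    } else read_dataset_csv(config$data_dir)
  })
  prep <- stage("preprocess",
                preprocess_dataset(raw, config$locus_params,
                                   missing_marker = if (!is.null(raw$config))
                                     raw$config$missing_marker else "./."))
  merged <- prep$merged
  fr <- merged$frame
  if (!all(fr$year <= config$train_cutoff | fr$year == config$test_year)) {
    drop <- fr$year > config$train_cutoff & fr$year != config$test_year
    keep_idx <- which(!drop)
    merged$frame <- fr[keep_idx, , drop = FALSE]
    merged$weather <- merged$weather[keep_idx, , , drop = FALSE]
    merged$genotype <- merged$genotype[keep_idx, , drop = FALSE]
    fr <- merged$frame
  }
  is_train <- fr$year <= config$train_cutoff
  training <- fr[is_train, c("state", "hybrid", "year", "yield")]
  if (nrow(training) == 0) stop("pipeline stage [split] failed: no training rows")

  feats <- stage("features", {
    aug <- add_yield_features(fr, training)
    merged$frame <- aug
    utils::write.csv(
      aug[, c("env", "hybrid", "state", "year", "sh_mean", "sh_max", "sh_min",
              "h_mean", "h_max", "h_min", "parent1_mean", "parent2_mean",
              "trend", "feature_provenance")],
      file.path(config$out_dir, "features.csv"), row.names = FALSE)
    merged
  })

  sub_merged <- function(idx) {
    list(frame = feats$frame[idx, , drop = FALSE],
         weather = feats$weather[idx, , , drop = FALSE],
         genotype = feats$genotype[idx, , drop = FALSE])
  }
  tr_md <- stage("prepare", prepare_model_data(sub_merged(which(is_train)),
                                               prep$loci))
  te_md <- stage("prepare", prepare_model_data(sub_merged(which(!is_train)),
                                               prep$loci, template = tr_md))
  if (length(te_md$y) == 0) stop("pipeline stage [split] failed: no test rows")

  nr <- config$xgb_nrounds
  preds <- list()
  models <- config$models
  need_parts <- any(c("multimodal", "ensemble") %in% models)
  stage("train", {
    if ("lasso" %in% models) {
      m <- fit_baseline("lasso", tr_md$flat, tr_md$y, config$model_cfg)
      preds[["lasso"]] <- predict(m, te_md$flat)
    }
    if ("rf" %in% models) {
      m <- fit_baseline("rf", tr_md$flat, tr_md$y, config$model_cfg,
                        seed = config$seed)
      preds[["rf"]] <- predict(m, te_md$flat)
    }
    if ("xgb" %in% models) {
      m <- fit_baseline("xgb", tr_md$flat, tr_md$y, config$model_cfg,
                        seed = config$seed, nrounds = nr)
      preds[["xgb"]] <- predict(m, te_md$flat)
    }
    if ("cnn" %in% models) {
      net <- build_single_modal(ncol(tr_md$flat), config$model_cfg)
      m <- fit_cnn_dnn(net, list(x = tr_md$flat), tr_md$y, config$model_cfg)
      preds[["cnn"]] <- predict(m, list(x = te_md$flat))
    }
    if (need_parts) {
      net <- build_multimodal(multimodal_shapes(tr_md), config$model_cfg)
      mm <- fit_cnn_dnn(net, tr_md$inputs, tr_md$y, config$model_cfg)
      pred_mm <- predict(mm, te_md$inputs)
      if ("multimodal" %in% models) preds[["multimodal"]] <- pred_mm
      if ("ensemble" %in% models) {
        rows_tr <- tr_md$frame
        over <- if (config$oversample)
          oversample_treatments(rows_tr, seed = config$seed) else rows_tr
        xgbm <- train_xgb_yield_features(over, tr_md$cat_levels,
                                         config$model_cfg, nrounds = nr,
                                         seed = config$seed)
        pred_xgb_te <- predict(xgbm, te_md$frame)
        # weight search on the held-out last training year
        val_year <- max(rows_tr$year)
        val_idx <- which(tr_md$frame$year == val_year)
        w <- if (length(val_idx) >= 2 && length(unique(tr_md$frame$year)) > 1) {
          fit_idx <- setdiff(seq_along(tr_md$y), val_idx)
          sub_tr <- lapply(tr_md$inputs, slice_input, idx = fit_idx)
          net_v <- build_multimodal(multimodal_shapes(tr_md), config$model_cfg)
          mm_v <- fit_cnn_dnn(net_v, sub_tr, tr_md$y[fit_idx],
                              config$model_cfg)
          pv_cnn <- predict(mm_v, lapply(tr_md$inputs, slice_input,
                                         idx = val_idx))
          rows_v <- tr_md$frame[fit_idx, , drop = FALSE]
          over_v <- if (config$oversample)
            oversample_treatments(rows_v, seed = config$seed) else rows_v
          xgb_v <- train_xgb_yield_features(over_v, tr_md$cat_levels,
                                            config$model_cfg, nrounds = nr,
                                            seed = config$seed)
          pv_xgb <- predict(xgb_v, tr_md$frame[val_idx, , drop = FALSE])
          grid_search_ensemble_weights(pv_xgb, pv_cnn, tr_md$y[val_idx])
        } else list(w_xgb = 0.1, w_cnn = 0.9)
        preds[["ensemble"]] <- ensemble_predict(w, pred_xgb_te, pred_mm)
        attr(preds, "ensemble_weights") <- c(w_xgb = w$w_xgb, w_cnn = w$w_cnn)
      }
    }
  })

  metrics <- stage("evaluate", {
    rows <- lapply(names(preds), function(nm) {
      r <- evaluate_by_treatment(te_md$y, preds[[nm]], te_md$frame$treatment)
      cbind(model = nm, r$overall)
    })
    overall <- do.call(rbind, rows)
    utils::write.csv(overall, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    bt <- lapply(names(preds), function(nm) {
      r <- evaluate_by_treatment(te_md$y, preds[[nm]], te_md$frame$treatment)
      cbind(model = nm, r$by_treatment)
    })
    utils::write.csv(do.call(rbind, bt),
                     file.path(config$out_dir, "metrics_by_treatment.csv"),
                     row.names = FALSE)
    overall
  })

  stage("classify", {
    stats <- summarize_hybrid_yields(
      cbind(fr[is_train, c("hybrid", "treatment")],
            yield = fr$yield[is_train]))
    cm <- build_class_matrix(stats)
    utils::write.csv(data.frame(hybrid = rownames(cm), cm,
                                check.names = FALSE),
                     file.path(config$out_dir, "class_matrix.csv"),
                     row.names = FALSE)
  })

  manifest <- list(seed = config$seed, train_cutoff = config$train_cutoff,
                   test_year = config$test_year, models = names(preds),
                   n_train = length(tr_md$y), n_test = length(te_md$y),
                   n_loci = length(prep$loci),
                   ensemble_weights = attr(preds, "ensemble_weights"),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  res <- list(metrics = metrics, predictions = preds, y_test = te_md$y,
              treatments = te_md$frame$treatment, loci = prep$loci)
  out <- config$out_dir
  attr(out, "result") <- res
  invisible(out)
}

#' Write a human-readable model-comparison report for a run
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Path of the written report (invisibly); the report lists models
#'   sorted by RMSE ascending plus the per-treatment breakdown.
#' @export
write_report <- function(run_dir) {
  mp <- file.path(run_dir, "metrics.csv")
  if (!file.exists(mp)) stop("missing metrics file: ", mp)
  m <- utils::read.csv(mp)
  m <- m[order(m$rmse), , drop = FALSE]
  lines <- c("Model comparison (test year)", "",
             utils::capture.output(print(
               cbind(model = m$model, format_metrics(m)), row.names = FALSE)))
  btp <- file.path(run_dir, "metrics_by_treatment.csv")
  if (file.exists(btp)) {
    bt <- utils::read.csv(btp)
    lines <- c(lines, "", "Per-treatment breakdown:",
               utils::capture.output(print(
                 cbind(model = bt$model, treatment = bt$treatment,
                       format_metrics(bt)), row.names = FALSE)))
  }
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
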