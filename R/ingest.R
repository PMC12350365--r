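# Loading and preprocessing of the six G2F-style tables: metadata imputation,
# planting-date conversion, weekly weather aggregation, the two-pass
# location/state imputation hierarchy, and the final join into one modeling
# frame keyed by Env (location_year) and Hybrid.

#' Split an Env key into location and year
#'
#' Env keys are "location_year" strings such as "LOC1_2018"; the year is the
#' final underscore-delimited token.
#'
#' @param env Character vector of Env keys.
#' @return data.frame with columns `env`, `location`, `year`.
#' @export
parse_env <- function(env) {
  m <- regmatches(env, regexpr("_[0-9]{4}$", env))
  if (length(m) != length(env) || any(!nzchar(m)))
    stop("Env keys must end in _YYYY: ", paste(utils::head(env[!grepl("_[0-9]{4}$", env)], 3), collapse = ", "))
  data.frame(env = env,
             location = sub("_[0-9]{4}$", "", env),
             year = as.integer(sub("^_", "", m)))
}

#' Impute missing treatment labels with the column mode
#'
#' The mode is computed over non-missing entries; ties are broken by taking
#' the lexicographically smallest label so imputation is deterministic.
#'
#' @param metadata data.frame with a `treatment` column (NA = missing).
#' @return The metadata with no missing treatment.
#' @export
impute_metadata <- function(metadata) {
  tr <- metadata$treatment
  if (all(is.na(tr))) stop("treatment column is entirely missing; cannot impute")
  if (anyNA(tr)) {
    tab <- table(tr[!is.na(tr)])
    mode_label <- sort(names(tab)[tab == max(tab)])[1]
    metadata$treatment[is.na(tr)] <- mode_label
  }
  metadata
}

#' Classify free-text issue comments into six categories
#'
#' A configurable keyword map over the categories animal attack, data issues,
#' drought, storm, no issues, and miscellaneous. First matching keyword wins;
#' empty or NA comments are "no issues"; anything unmatched is
#' "miscellaneous".
#'
#' @param comments Character vector of raw comments.
#' @param keyword_map Named list: category -> regex of keywords.
#' @return Character vector of issue classes.
#' @export
classify_issues <- function(comments,
                            keyword_map = list(
                              `animal attack` = "deer|bird|raccoon|animal|wildlife",
                              `data issues`   = "data|sensor|record|mislabel",
                              drought         = "drought|dry spell|water stress",
                              storm           = "storm|wind|hail|flood|lodging"
                            )) {
  out <- rep("miscellaneous", length(comments))
  out[is.na(comments) | !nzchar(trimws(comments))] <- "no issues"
  todo <- out == "miscellaneous"
  for (cls in names(keyword_map)) {
    hit <- todo & grepl(keyword_map[[cls]], comments, ignore.case = TRUE)
    out[hit] <- cls
    todo <- todo & !hit
  }
  out
}

#' Convert a planting date to day-of-year
#'
#' 1-based ordinal day; leap years honored (2020-03-01 is day 61).
#'
#' @param date ISO "YYYY-MM-DD" strings or Date objects.
#' @return Integer day-of-year.
#' @export
planting_date_to_doy <- function(date) {
  d <- tryCatch(as.Date(date),
                error = function(e) as.Date(rep(NA, length(date))))
  if (anyNA(d)) stop("unparseable date: ",
                     paste(utils::head(date[is.na(d)], 3), collapse = ", "))
  as.integer(format(d, "%j"))
}

#' Aggregate daily weather into 48 weekly values per feature
#'
#' The long table (Env, date, 16 features) is pivoted wide per Env and day of
#' year, then week w summarizes days 7(w-1)+1 .. 7w for w = 1..48; days 337
#' onward are discarded. Default statistic is the mean; precipitation-like
#' features can use sum/min/max via `aggregator`.
#'
#' @param daily Long data.frame: columns `env`, `date` (Date or ISO string),
#'   then one column per weather feature.
#' @param aggregator Single statistic ("mean", "sum", "min", "max") or a
#'   named character vector giving a per-feature override.
#' @return List of class `weekly_weather`: one 48 x F matrix per Env
#'   (weeks in rows, features in columns).
#' @export
weather_to_weekly <- function(daily, aggregator = "mean") {
  feat_cols <- setdiff(names(daily), c("env", "date"))
  if (length(feat_cols) == 0) stop("no weather feature columns found")
  doy <- planting_date_to_doy(daily$date)
  agg_of <- function(f) {
    a <- if (length(aggregator) == 1 && is.null(names(aggregator))) aggregator
         else if (f %in% names(aggregator)) aggregator[[f]] else "mean"
    match.fun(a)
  }
  envs <- unique(daily$env)
  # coverage check: each Env needs days 1..336 at least
  n_days <- tapply(doy, daily$env, function(d) length(unique(d[d <= 336])))
  short <- names(n_days)[n_days < 336]
  if (length(short) > 0)
    stop("insufficient daily coverage (need days 1..336) for Env: ",
         paste(short, collapse = ", "))
  week <- (doy - 1L) %/% 7L + 1L
  keep <- week <= 48L
  out <- lapply(envs, function(e) {
    sel <- daily$env == e & keep
    w <- week[sel]
    mat <- vapply(feat_cols, function(f) {
      v <- daily[[f]][sel]
      as.numeric(tapply(v, w, agg_of(f)))
    }, numeric(48))
    dimnames(mat) <- list(week = 1:48, feature = feat_cols)
    if (anyNA(mat)) stop("missing weekly weather cells for Env ", e)
    mat
  })
  names(out) <- envs
  structure(out, class = "weekly_weather")
}

#' Two-pass location/state mean imputation
#'
#' Pass 1 fills each missing cell with the mean of the same feature at the
#' same location over other years; pass 2 fills what remains with the state
#' mean. Non-missing cells are never altered. Cells still missing after both
#' passes are flagged (`still_missing` attribute) with a warning.
#'
#' @param table data.frame with `location`, `state`, `year` key columns.
#' @param feature_cols Character vector of columns to impute.
#' @return The table imputed, with attribute `imputation_log` counting fills
#'   per feature per pass.
#' @export
impute_by_location_hierarchy <- function(table, feature_cols) {
  stopifnot(all(c("location", "state", "year") %in% names(table)),
            all(feature_cols %in% names(table)))
  log <- data.frame(feature = feature_cols, pass1 = 0L, pass2 = 0L,
                    unresolved = 0L)
  flagged <- rep(FALSE, nrow(table))
  for (k in seq_along(feature_cols)) {
    f <- feature_cols[k]
    v <- table[[f]]
    miss <- is.na(v)
    if (any(miss)) {
      loc_mean <- tapply(v, table$location, mean, na.rm = TRUE)
      fill <- loc_mean[table$location[miss]]
      v[miss] <- ifelse(is.nan(fill), NA, fill)
      log$pass1[k] <- sum(miss) - sum(is.na(v))
    }
    miss2 <- is.na(v)
    if (any(miss2)) {
      st_mean <- tapply(v, table$state, mean, na.rm = TRUE)
      fill <- st_mean[table$state[miss2]]
      v[miss2] <- ifelse(is.nan(fill), NA, fill)
      log$pass2[k] <- sum(miss2) - sum(is.na(v))
    }
    log$unresolved[k] <- sum(is.na(v))
    flagged <- flagged | is.na(v)
    table[[f]] <- v
  }
  if (any(log$unresolved > 0))
    warning("features entirely missing within a state after both passes: ",
            paste(log$feature[log$unresolved > 0], collapse = ", "))
  attr(table, "imputation_log") <- log
  attr(table, "row_flagged") <- flagged
  table
}

#' Join the six preprocessed tables into one modeling frame
#'
#' Inner join on Env for metadata, weekly weather, soil, and environmental
#' features; left join on Hybrid for genotype. Rows whose hybrid has no
#' genotype row are kept but flagged (`genotype_missing`) so model training
#' can exclude them. The join is order-independent.
#'
#' @param trait data.frame: `env`, `hybrid`, `yield`.
#' @param metadata data.frame keyed by `env` (treatment, planting_doy, ...).
#' @param weekly [weather_to_weekly()] output.
#' @param soil data.frame keyed by `env` with soil feature columns.
#' @param envsim data.frame keyed by `env` with environmental features.
#' @param genotype Encoded dosage matrix with hybrid row names.
#' @return A `merged_frame` list: `frame` (trait + metadata + soil + envsim
#'   columns + `genotype_missing` flag), `weather` (n x 48 x F array aligned
#'   to rows), `genotype` (n x L matrix, NA rows where missing).
#' @export
join_all <- function(trait, metadata, weekly, soil, envsim, genotype) {
  for (nm in c("metadata", "soil", "envsim")) {
    tb <- get(nm)
    if (anyDuplicated(tb$env))
      stop("duplicate Env keys in ", nm, " table")
  }
  if (nrow(trait) == 0) {
    return(structure(list(frame = trait, weather = NULL, genotype = NULL),
                     class = "merged_frame"))
  }
  frame <- merge(trait, metadata, by = "env", sort = FALSE)
  frame <- merge(frame, soil, by = "env", sort = FALSE)
  frame <- merge(frame, envsim, by = "env", sort = FALSE)
  missing_env <- setdiff(trait$env, frame$env)
  if (length(missing_env) > 0)
    stop("Env keys missing from a source table: ",
         paste(utils::head(missing_env, 5), collapse = ", "))
  # deterministic row order regardless of input order
  frame <- frame[order(frame$env, frame$hybrid), , drop = FALSE]
  rownames(frame) <- NULL
  wk <- weekly[frame$env]
  if (any(vapply(wk, is.null, logical(1))))
    stop("weekly weather missing for some Env")
  weather <- array(NA_real_, dim = c(nrow(frame), 48, ncol(wk[[1]])),
                   dimnames = list(NULL, NULL, colnames(wk[[1]])))
  for (i in seq_len(nrow(frame))) weather[i, , ] <- wk[[i]]
  gmat <- matrix(NA_real_, nrow(frame), ncol(genotype),
                 dimnames = list(NULL, colnames(genotype)))
  hit <- frame$hybrid %in% rownames(genotype)
  gmat[hit, ] <- genotype[frame$hybrid[hit], , drop = FALSE]
  frame$genotype_missing <- !hit
  structure(list(frame = frame, weather = weather, genotype = gmat),
            class = "merged_frame")
}
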