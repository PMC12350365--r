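# Engineered yield features: per state-hybrid and per-hybrid summary yields,
# parent mean yields from the "Parent1/Parent2" hybrid naming, and a per-state
# linear yield trend over training years. Everything here is computed from
# training rows only; the caller enforces the temporal cutoff.

#' State x hybrid yield summary features
#'
#' One row per observed (state, hybrid) combination with mean, maximum, and
#' minimum training yield and the supporting row count.
#'
#' @param training data.frame with `state`, `hybrid`, `yield` columns,
#'   already restricted to training years.
#' @return data.frame: state, hybrid, mean_yield, max_yield, min_yield, support.
#' @export
state_hybrid_stats <- function(training) {
  if (nrow(training) == 0) stop("empty training set")
  key <- interaction(training$state, training$hybrid, drop = TRUE, sep = "\r")
  agg <- function(f) as.numeric(tapply(training$yield, key, f))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    state = vapply(parts, `[`, "", 1),
    hybrid = vapply(parts, `[`, "", 2),
    mean_yield = agg(mean), max_yield = agg(max), min_yield = agg(min),
    support = as.integer(tapply(training$yield, key, length))
  )
  out[order(out$state, out$hybrid), , drop = FALSE]
}

#' Impute yield features for unseen state-hybrid combinations
#'
#' For a combination absent from training, each statistic column is imputed
#' as the average of the state-level mean and state-level mode of that
#' column. The mode of a continuous column is taken on values rounded to one
#' decimal, most frequent first, smallest value on ties. If the state itself
#' was unseen in training the global column mean is used instead (flagged
#' "fallback").
#'
#' @param feature_table Output of [state_hybrid_stats()].
#' @param state State label of the unseen combination.
#' @return One-row data.frame of imputed mean/max/min yield with a
#'   `provenance` column ("imputed" or "fallback").
#' @export
impute_unseen_combo <- function(feature_table, state) {
  cols <- c("mean_yield", "max_yield", "min_yield")
  rows <- feature_table[feature_table$state == state, , drop = FALSE]
  if (nrow(rows) == 0) {
    out <- as.data.frame(lapply(feature_table[cols], mean))
    out$provenance <- "fallback"
    return(out)
  }
  out <- as.data.frame(lapply(rows[cols], function(v) {
    (mean(v) + mode_1dp(v)) / 2
  }))
  out$provenance <- "imputed"
  out
}

# Mode of a continuous vector on a 0.1 Mg/ha grid; smallest value on ties.
mode_1dp <- function(v) {
  r <- round(v, 1)
  tab <- table(r)
  as.numeric(names(tab)[tab == max(tab)])[1]
}

#' Per-hybrid and per-parent yield features
#'
#' Hybrid labels follow the F1 naming "Parent1/Parent2". Per hybrid:
#' mean/max/min training yield. Per parent: mean yield over every training
#' row whose hybrid carries that parent on either side. Hybrids without "/"
#' in the label get NA parent features (flagged).
#'
#' @param training data.frame with `hybrid`, `yield`.
#' @return List: `hybrid` (hybrid, mean/max/min yield, support, parent1,
#'   parent2, parent1_mean, parent2_mean), `parent` (parent, mean_yield,
#'   support).
#' @export
hybrid_and_parent_stats <- function(training) {
  if (nrow(training) == 0) stop("empty training set")
  key <- factor(training$hybrid)
  hs <- data.frame(
    hybrid = levels(key),
    mean_yield = as.numeric(tapply(training$yield, key, mean)),
    max_yield = as.numeric(tapply(training$yield, key, max)),
    min_yield = as.numeric(tapply(training$yield, key, min)),
    support = as.integer(tapply(training$yield, key, length))
  )
  toks <- strsplit(hs$hybrid, "/", fixed = TRUE)
  two <- lengths(toks) == 2
  hs$parent1 <- ifelse(two, vapply(toks, `[`, "", 1), NA)
  hs$parent2 <- ifelse(two, vapply(toks, function(t) t[min(2, length(t))], ""), NA)
  row_toks <- strsplit(training$hybrid, "/", fixed = TRUE)
  long <- data.frame(
    parent = unlist(row_toks),
    yield = rep(training$yield, lengths(row_toks))
  )
  long <- long[rep(lengths(row_toks) == 2, lengths(row_toks)), , drop = FALSE]
  pk <- factor(long$parent)
  parent <- data.frame(
    parent = levels(pk),
    mean_yield = as.numeric(tapply(long$yield, pk, mean)),
    support = as.integer(tapply(long$yield, pk, length))
  )
  idx <- function(p) match(p, parent$parent)
  hs$parent1_mean <- parent$mean_yield[idx(hs$parent1)]
  hs$parent2_mean <- parent$mean_yield[idx(hs$parent2)]
  list(hybrid = hs, parent = parent)
}

#' Fit the per-state linear yield trend
#'
#' Ordinary least squares of yield on calendar year, fitted at row level
#' (every trial contributes one point) within each state. A state observed
#' in a single year gets slope 0 and intercept equal to its mean yield
#' (recorded in the `degenerate` column).
#'
#' @param training data.frame with `state`, `year`, `yield`.
#' @param year_origin Subtracted from year before fitting; default 0 uses
#'   calendar years directly (set to the first training year to index from 0).
#' @return data.frame of class `trend_model`: state, intercept, slope,
#'   n_years, degenerate; the `year_origin` is carried as an attribute.
#' @export
fit_state_trend <- function(training, year_origin = 0) {
  if (nrow(training) == 0) stop("empty training set")
  states <- sort(unique(training$state))
  rows <- lapply(states, function(s) {
    d <- training[training$state == s, , drop = FALSE]
    yr <- d$year - year_origin
    if (length(unique(yr)) < 2) {
      data.frame(state = s, intercept = mean(d$yield), slope = 0,
                 n_years = length(unique(yr)), degenerate = TRUE)
    } else {
      fit <- stats::lm(yield ~ yr, data = data.frame(yield = d$yield, yr = yr))
      data.frame(state = s, intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 n_years = length(unique(yr)), degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "year_origin") <- year_origin
  class(out) <- c("trend_model", "data.frame")
  out
}

#' Predict the yield trend for a state and year
#'
#' @param model A [fit_state_trend()] result.
#' @param state State label(s).
#' @param year Calendar year(s).
#' @return Predicted trend yield (Mg/ha), affine in year.
#' @export
predict_trend <- function(model, state, year) {
  i <- match(state, model$state)
  if (anyNA(i)) stop("no trend fitted for state: ",
                     paste(unique(state[is.na(i)]), collapse = ", "))
  model$intercept[i] + model$slope[i] * (year - attr(model, "year_origin"))
}

#' Assemble the engineered feature columns for a modeling frame
#'
#' Attaches state-hybrid mean/max/min (imputed via [impute_unseen_combo()]
#' for unseen combinations), hybrid-level mean/max/min, parent means (parent
#' pool mean for unseen parents), and the state yield trend evaluated at the
#' row's year. All statistics come from `training` only.
#'
#' @param frame data.frame with `state`, `hybrid`, `year` columns.
#' @param training Training rows (`state`, `hybrid`, `year`, `yield`).
#' @return `frame` with columns sh_mean/sh_max/sh_min, h_mean/h_max/h_min,
#'   parent1_mean, parent2_mean, trend and a `feature_provenance` column.
#' @export
add_yield_features <- function(frame, training) {
  sh <- state_hybrid_stats(training)
  hp <- hybrid_and_parent_stats(training)
  trend <- fit_state_trend(training)
  key <- paste(frame$state, frame$hybrid, sep = "\r")
  shkey <- paste(sh$state, sh$hybrid, sep = "\r")
  i <- match(key, shkey)
  frame$sh_mean <- sh$mean_yield[i]
  frame$sh_max <- sh$max_yield[i]
  frame$sh_min <- sh$min_yield[i]
  frame$feature_provenance <- ifelse(is.na(i), "imputed", "observed")
  for (s in unique(frame$state[is.na(i)])) {
    imp <- impute_unseen_combo(sh, s)
    sel <- is.na(i) & frame$state == s
    frame$sh_mean[sel] <- imp$mean_yield
    frame$sh_max[sel] <- imp$max_yield
    frame$sh_min[sel] <- imp$min_yield
    if (imp$provenance == "fallback") frame$feature_provenance[sel] <- "fallback"
  }
  j <- match(frame$hybrid, hp$hybrid$hybrid)
  hm <- mean(hp$hybrid$mean_yield)
  frame$h_mean <- ifelse(is.na(j), hm, hp$hybrid$mean_yield[j])
  frame$h_max <- ifelse(is.na(j), mean(hp$hybrid$max_yield), hp$hybrid$max_yield[j])
  frame$h_min <- ifelse(is.na(j), mean(hp$hybrid$min_yield), hp$hybrid$min_yield[j])
  # parent means for any hybrid name, seen or not, via the parent pool
  toks <- strsplit(frame$hybrid, "/", fixed = TRUE)
  pmean <- function(k) {
    p <- vapply(toks, function(t) if (length(t) == 2) t[k] else NA_character_, "")
    v <- hp$parent$mean_yield[match(p, hp$parent$parent)]
    ifelse(is.na(v), mean(hp$parent$mean_yield), v)
  }
  frame$parent1_mean <- pmean(1)
  frame$parent2_mean <- pmean(2)
  known_state <- frame$state %in% trend$state
  frame$trend <- NA_real_
  frame$trend[known_state] <- predict_trend(trend, frame$state[known_state],
                                            frame$year[known_state])
  frame$trend[!known_state] <- mean(training$yield)
  frame
}
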