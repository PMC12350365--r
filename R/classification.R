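# Empirical rule-based hybrid yield classification: summarize each
# hybrid x treatment yield distribution, map it to one of six classes via
# fixed thresholds, and render the class matrix as a heatmap.

YIELD_CLASSES <- c("extremely low", "low", "moderate", "wide range", "high",
                   "extremely high")

#' Classification rule thresholds
#'
#' The rule uses two yield thresholds and a span: yields never above `t_low`
#' are extremely low, never below `t_high` extremely high, distributions
#' straddling both thresholds with a span above `wide_span` are wide range,
#' and the median decides high/low/moderate otherwise. Defaults (6, 10, 8
#' Mg/ha) are a documented reconstruction consistent with drought yields
#' splitting around 6 and 12 Mg/ha; all are configurable.
#'
#' @param t_low Low-yield threshold (Mg/ha, default 6).
#' @param t_high High-yield threshold (Mg/ha, default 10).
#' @param wide_span Minimum max-min span for "wide range" (Mg/ha, default 8).
#' @param use_mean Substitute the mean for the median in the rule branches.
#' @return List of class `class_rule`.
#' @export
class_rule <- function(t_low = 6, t_high = 10, wide_span = 8,
                       use_mean = FALSE) {
  if (t_low >= t_high) stop("t_low must be below t_high")
  if (wide_span <= 0) stop("wide_span must be positive")
  structure(list(t_low = t_low, t_high = t_high, wide_span = wide_span,
                 use_mean = use_mean),
            class = "class_rule")
}

#' Summarize yields per hybrid and treatment
#'
#' @param rows data.frame with `hybrid`, `treatment`, `yield`.
#' @return data.frame: hybrid, treatment, max, min, median, mean, n.
#' @export
summarize_hybrid_yields <- function(rows) {
  if (nrow(rows) == 0) stop("empty input")
  key <- interaction(rows$hybrid, rows$treatment, drop = TRUE, sep = "\r")
  agg <- function(f) as.numeric(tapply(rows$yield, key, f))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    hybrid = vapply(parts, `[`, "", 1),
    treatment = vapply(parts, `[`, "", 2),
    max = agg(max), min = agg(min), median = agg(stats::median),
    mean = agg(mean), n = as.integer(tapply(rows$yield, key, length))
  )
  out[order(out$hybrid, out$treatment), , drop = FALSE]
}

#' Classify one yield distribution
#'
#' First matching branch in fixed order: (1) max <= t_low -> extremely low;
#' (2) min >= t_high -> extremely high; (3) min < t_low and max > t_high and
#' max - min > wide_span -> wide range; (4) central value >= t_high -> high;
#' (5) central value <= t_low -> low; (6) moderate. The central value is the
#' median (the mean when `rule$use_mean`). Total and deterministic.
#'
#' @param stats One row (or vectorized columns) with max, min, median, mean.
#' @param rule A [class_rule()].
#' @return Character class label(s).
#' @export
classify_yield <- function(stats, rule = class_rule()) {
  central <- if (rule$use_mean) stats$mean else stats$median
  out <- rep("moderate", length(central))
  done <- rep(FALSE, length(central))
  hit <- function(cond, label) {
    sel <- !done & cond
    out[sel] <<- label
    done <<- done | sel
  }
  hit(stats$max <= rule$t_low, "extremely low")
  hit(stats$min >= rule$t_high, "extremely high")
  hit(stats$min < rule$t_low & stats$max > rule$t_high &
        (stats$max - stats$min) > rule$wide_span, "wide range")
  hit(central >= rule$t_high, "high")
  hit(central <= rule$t_low, "low")
  out
}

#' Build the hybrid x treatment class matrix
#'
#' Rows = union of hybrids, columns = union of treatments; unobserved cells
#' are "no data".
#'
#' @param stats A [summarize_hybrid_yields()] table.
#' @param rule A [class_rule()].
#' @return Character matrix of class labels.
#' @export
build_class_matrix <- function(stats, rule = class_rule()) {
  if (nrow(stats) == 0) stop("empty stats table")
  hybrids <- sort(unique(stats$hybrid))
  treatments <- sort(unique(stats$treatment))
  m <- matrix("no data", length(hybrids), length(treatments),
              dimnames = list(hybrids, treatments))
  cls <- classify_yield(stats, rule)
  m[cbind(match(stats$hybrid, hybrids), match(stats$treatment, treatments))] <- cls
  m
}

#' Render the class matrix as a heatmap
#'
#' Fixed 6+1 color legend: extremely low in red through extremely high in
#' blue, grey for "no data".
#'
#' @param matrix A [build_class_matrix()] result.
#' @param path Output image path (.png or .pdf).
#' @param width,height Device size in inches.
#' @return Invisibly, the ggplot object (also written to `path` if given).
#' @export
render_heatmap <- function(matrix, path = NULL, width = 7, height = 7) {
  df <- expand.grid(hybrid = rownames(matrix), treatment = colnames(matrix),
                    stringsAsFactors = FALSE)
  df$class <- factor(matrix[cbind(df$hybrid, df$treatment)],
                     levels = c(YIELD_CLASSES, "no data"))
  cols <- c(`extremely low` = "#b2182b", low = "#ef8a62", moderate = "#fddbc7",
            `wide range` = "#f7f7f7", high = "#67a9cf",
            `extremely high` = "#2166ac", `no data` = "grey80")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$treatment, y = .data$hybrid,
                                        fill = .data$class)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::labs(x = "Treatment", y = "Hybrid", fill = "Yield class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) ggplot2::ggsave(path, p, width = width, height = height)
  invisible(p)
}
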