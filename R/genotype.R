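# Genotype call encoding, locus filtering, and subsampling.
#
# Calls arrive as diploid strings ("0/0", "0/1", ...). The dosage code set is
# {0, 0.5, 1} for the common biallelic calls plus a single sentinel 0.15 for
# every rarer multi-allelic call; missingness propagates and is handled by a
# locus-level drop policy before the informative-locus filter runs.

#' Encode genotype call strings to numeric dosages
#'
#' "0/0" -> 0; "0/1" or "1/0" -> 0.5; "1/1" -> 1; any other non-missing call
#' (e.g. "2/0", "2/2") -> 0.15. Missing markers stay missing (NA). Numeric
#' input already restricted to the code set passes through unchanged;
#' numeric values outside the code set are an error.
#'
#' @param calls A matrix or data.frame of call strings, hybrids in rows and
#'   loci in columns (row names = hybrid IDs), or a single character vector.
#' @param missing_markers Strings treated as missing (default "./." and "").
#' @return A numeric matrix of the same shape with entries in
#'   \{0, 0.15, 0.5, 1\} or NA, class `genotype_matrix`.
#' @export
encode_calls <- function(calls, missing_markers = c("./.", "", NA)) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (is.numeric(calls)) {
    ok <- is.na(calls) | calls %in% c(0, 0.15, 0.5, 1)
    if (!all(ok)) stop("numeric input contains values outside the dosage code set")
    return(structure(calls, class = c("genotype_matrix", class(calls))))
  }
  dm <- dim(calls)
  dn <- dimnames(calls)
  x <- as.character(calls)
  out <- rep(0.15, length(x))
  out[x == "0/0"] <- 0
  out[x == "0/1" | x == "1/0"] <- 0.5
  out[x == "1/1"] <- 1
  out[x %in% missing_markers | is.na(x)] <- NA_real_
  if (!is.null(dm)) { dim(out) <- dm; dimnames(out) <- dn }
  structure(out, class = c("genotype_matrix", class(out)))
}

#' Drop loci with missing dosages
#'
#' Default policy removes every locus with at least one missing entry.
#' A fractional `threshold` instead removes loci whose missing fraction
#' exceeds it (e.g. 0.8 keeps a locus that is 10% missing).
#'
#' @param g Encoded dosage matrix (hybrids x loci).
#' @param policy "any-missing" (default) or "fraction".
#' @param threshold Missing-fraction cutoff for `policy = "fraction"`.
#' @return The filtered matrix with attribute `removed`: a data.frame of the
#'   removed loci and their missing fractions.
#' @export
drop_missing_loci <- function(g, policy = c("any-missing", "fraction"),
                              threshold = 0.8) {
  policy <- match.arg(policy)
  g <- as_dosage_matrix(g)
  miss_frac <- colMeans(is.na(g))
  drop <- if (policy == "any-missing") miss_frac > 0 else miss_frac > threshold
  if (all(drop))
    stop("all loci removed by missing-value policy; relax the policy ",
         "(e.g. policy = 'fraction')")
  report <- data.frame(locus = colnames(g)[drop],
                       missing_fraction = unname(miss_frac[drop]))
  out <- g[, !drop, drop = FALSE]
  attr(out, "removed") <- report
  structure(out, class = c("genotype_matrix", "matrix", "array"))
}

#' Locus filter parameters
#'
#' The source cohort of 4,928 hybrids used absolute counts (fewer than 4,000
#' hybrids with dosage 0; at least 1,000 with dosage 0.5); those are carried
#' as fractions of cohort size so the rule scales to any number of hybrids.
#'
#' @param max_zero_fraction Keep a locus only if its fraction of dosage-0
#'   entries is strictly below this (default 4000/4928).
#' @param min_het_fraction Keep only if the fraction of dosage-0.5 entries is
#'   at least this (default 1000/4928).
#' @param forbid_other_code If TRUE (default) a locus with any 0.15 entry is
#'   excluded.
#' @param n_sample Number of loci to subsample downstream (default 300).
#' @param seed Seed for the subsample.
#' @return List of class `locus_filter_params`.
#' @export
locus_filter_params <- function(max_zero_fraction = 4000 / 4928,
                                min_het_fraction = 1000 / 4928,
                                forbid_other_code = TRUE,
                                n_sample = 300, seed = 1L) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction <= 1,
            min_het_fraction > 0, min_het_fraction <= 1,
            n_sample >= 1)
  structure(list(max_zero_fraction = max_zero_fraction,
                 min_het_fraction = min_het_fraction,
                 forbid_other_code = forbid_other_code,
                 n_sample = as.integer(n_sample), seed = as.integer(seed)),
            class = "locus_filter_params")
}

#' Select informative loci
#'
#' Keeps locus j iff count(dosage 0) < max_zero_fraction * H (strict) AND
#' count(dosage 0.5) >= min_het_fraction * H AND, when `forbid_other_code`,
#' no entry equals 0.15. H is the number of hybrids. Input order preserved.
#'
#' @param g Complete (no missing) dosage matrix.
#' @param params A [locus_filter_params()] object.
#' @return Character vector of kept locus labels (empty, with a warning, if
#'   none qualify).
#' @export
select_informative_loci <- function(g, params = locus_filter_params()) {
  g <- as_dosage_matrix(g)
  if (anyNA(g)) stop("matrix contains missing dosages; run drop_missing_loci first")
  H <- nrow(g)
  n0 <- colSums(g == 0)
  nhet <- colSums(g == 0.5)
  nother <- colSums(g == 0.15)
  keep <- (n0 < params$max_zero_fraction * H) &
    (nhet >= params$min_het_fraction * H)
  if (params$forbid_other_code) keep <- keep & (nother == 0)
  if (!any(keep)) {
    warning("no locus passed the informative-locus filter")
    return(character(0))
  }
  colnames(g)[keep]
}

#' Randomly subsample loci
#'
#' Uniform sample without replacement of `min(n_sample, length(kept))` loci;
#' deterministic for a given seed.
#'
#' @param kept Character vector of candidate locus labels.
#' @param n_sample Target number of loci.
#' @param seed Integer seed.
#' @return Character vector of sampled locus labels.
#' @export
sample_loci <- function(kept, n_sample = 300, seed = 1L) {
  if (length(kept) == 0) stop("no loci to sample from")
  n <- min(n_sample, length(kept))
  with_seed(seed, sample(kept, n))
}

as_dosage_matrix <- function(g) {
  if (is.data.frame(g)) g <- as.matrix(g)
  if (!is.numeric(g)) stop("expected an encoded (numeric) dosage matrix")
  if (is.null(colnames(g))) colnames(g) <- paste0("L", seq_len(ncol(g)))
  g
}

# Run expr under a local RNG seed without disturbing the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
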