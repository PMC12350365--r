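# Synthetic G2F-shaped data generator. Emits the six tables of a
# multi-environment maize trial release (trait, metadata, daily weather,
# soil, simulated environmental features, genotype call strings) with known
# injected effects so the whole pipeline is testable end-to-end. The
# generator emulates table shapes, keys, missingness, and a G x E x M yield
# signal; it does not attempt realistic weather dynamics or crop physiology.

TREATMENT_LEVELS <- c("standard", "drought", "irrigated", "disease trial",
                      "early planting", "late planting", "late stressed",
                      "dryland")

#' Configuration for the synthetic G2F-like dataset
#'
#' Defaults give a desk-scale cohort: 5 states x 2 locations over 2014-2021
#' (2021 the held-out year), 60 hybrids, 120 loci. The yield model is
#' baseline + state effect + additive locus effects + treatment offset -
#' late-planting penalty + Gaussian noise, clipped at 0. The baseline of
#' 9.44 Mg/ha matches a typical multi-environment training mean.
#'
#' @param n_states Number of states.
#' @param envs_per_state Locations per state (each location appears in every
#'   year, giving `envs_per_state * n_years` Envs per state).
#' @param years Inclusive integer year range.
#' @param n_hybrids Number of hybrids ("P<i>/P<j>" crosses).
#' @param n_loci Number of genotype loci.
#' @param n_days Daily weather span per Env (default 365).
#' @param treatment_classes Treatment labels in use.
#' @param missing_rates Named list of per-table missing-cell fractions
#'   (metadata treatment, soil, envsim, genotype).
#' @param effect_sizes Named list: `state_sd` (sd of state effects, Mg/ha),
#'   `locus_effect` (Mg/ha per dosage unit at each causal locus),
#'   `n_causal_loci`, `planting_penalty` (Mg/ha per day past the window),
#'   `planting_window_end` (day of year), `treatment_offsets` (named, Mg/ha),
#'   `noise_sd` (Mg/ha), `baseline` (Mg/ha).
#' @param frac_hybrids_per_env Fraction of hybrids planted in each Env.
#' @param genotype_coverage Fraction of trait hybrids present in the
#'   genotype table (1 = all).
#' @param call_mix Named probabilities over the ten call strings.
#' @param missing_marker Genotype missing marker (default "./.").
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_states = 5L, envs_per_state = 2L, years = 2014:2021,
    n_hybrids = 60L, n_loci = 500L, n_days = 365L,
    treatment_classes = TREATMENT_LEVELS,
    missing_rates = list(metadata = 0.05, soil = 0.05, envsim = 0.05,
                         genotype = 0.01),
    effect_sizes = list(state_sd = 1.5, locus_effect = 0.3, n_causal_loci = 10L,
                        planting_penalty = 0.05, planting_window_end = 140L,
                        treatment_offsets = c(standard = 0, drought = -2.5,
                                              irrigated = 0.5,
                                              `disease trial` = -1.5,
                                              `early planting` = -0.5,
                                              `late planting` = -1,
                                              `late stressed` = -2,
                                              dryland = -1),
                        noise_sd = 1, baseline = 9.44),
    frac_hybrids_per_env = 0.6,
    genotype_coverage = 1,
    call_mix = c(`0/0` = 0.42, `0/1` = 0.26, `1/0` = 0.10, `1/1` = 0.18,
                 `2/0` = 0.008, `0/2` = 0.008, `2/1` = 0.006, `1/2` = 0.006,
                 `2/2` = 0.006, `3/0` = 0.006),
    missing_marker = "./.",
    seed = 1L) {
  cfg <- list(n_states = as.integer(n_states),
              envs_per_state = as.integer(envs_per_state),
              years = as.integer(years), n_hybrids = as.integer(n_hybrids),
              n_loci = as.integer(n_loci), n_days = as.integer(n_days),
              treatment_classes = treatment_classes,
              missing_rates = missing_rates, effect_sizes = effect_sizes,
              frac_hybrids_per_env = frac_hybrids_per_env,
              genotype_coverage = genotype_coverage,
              call_mix = call_mix, missing_marker = missing_marker,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_states, cfg$envs_per_state, cfg$n_hybrids, cfg$n_loci,
              cfg$n_days)
  if (any(counts < 1)) stop("all counts must be >= 1")
  mr <- unlist(cfg$missing_rates)
  if (any(mr < 0 | mr > 1)) stop("missing_rates must lie in [0, 1]")
  if (cfg$effect_sizes$noise_sd < 0) stop("noise sd must be >= 0")
  if (abs(sum(cfg$call_mix) - 1) > 1e-8) stop("call_mix must sum to 1")
  if (any(cfg$call_mix < 0)) stop("call_mix probabilities must be nonnegative")
  invisible(cfg)
}

#' Generate genotype call strings
#'
#' Draws diploid call strings from the ten-level mix ("0/0" ... "3/0") and
#' masks cells with the missing marker at `missing_rate`. Under the default
#' mix, calls outside \{"0/0","0/1","1/0","1/1"\} carry under 5% of the mass.
#'
#' @param n_hybrids,n_loci Table dimensions.
#' @param call_mix Named probability vector over call strings (must sum to 1).
#' @param missing_rate Fraction of cells masked as missing.
#' @param missing_marker Marker string (default "./.").
#' @param seed Integer seed.
#' @param hybrids Optional row names; defaults to "P1/P2"-style crosses.
#' @return Character matrix (hybrids x loci) of call strings.
#' @export
generate_genotype_calls <- function(n_hybrids, n_loci,
                                    call_mix = synthetic_config()$call_mix,
                                    missing_rate = 0, missing_marker = "./.",
                                    seed = 1L, hybrids = NULL) {
  if (any(call_mix < 0)) stop("call_mix probabilities must be nonnegative")
  if (abs(sum(call_mix) - 1) > 1e-8) stop("call_mix must sum to 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (is.null(hybrids)) hybrids <- default_hybrid_names(n_hybrids)
  with_seed(seed, {
    calls <- matrix(sample(names(call_mix), n_hybrids * n_loci, replace = TRUE,
                           prob = call_mix),
                    nrow = n_hybrids,
                    dimnames = list(hybrids, paste0("L", seq_len(n_loci))))
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(calls)) < missing_rate, nrow = n_hybrids)
      calls[mask] <- missing_marker
    }
    calls
  })
}

# Hybrid names "P1/P2", "P1/P3", ... cycling over a small parent pool.
default_hybrid_names <- function(n_hybrids) {
  n_parents <- max(4L, ceiling((1 + sqrt(1 + 8 * n_hybrids)) / 2))
  combos <- utils::combn(paste0("P", seq_len(n_parents)), 2)
  paste(combos[1, seq_len(n_hybrids)], combos[2, seq_len(n_hybrids)], sep = "/")
}

#' Inject yield from the ground-truth effect record
#'
#' yield = baseline + state effect + sum(locus effect x dosage) + treatment
#' offset - planting penalty x max(0, planting_doy - window end) + N(0, sd),
#' clipped at 0.
#'
#' @param truth List: `baseline`, `state_effects` (named), `locus_effects`
#'   (named, Mg/ha per dosage), `treatment_offsets` (named),
#'   `planting_penalty`, `planting_window_end`, `noise_sd`.
#' @param design data.frame: `state`, `hybrid`, `treatment`, `planting_doy`.
#' @param genotypes Encoded dosage matrix with hybrid row names covering the
#'   design hybrids (used for the causal loci).
#' @param seed Integer seed for the noise draw.
#' @return Numeric yield vector (Mg/ha), nonnegative.
#' @export
inject_yield <- function(truth, design, genotypes, seed = 1L) {
  if (!all(design$state %in% names(truth$state_effects)))
    stop("unknown state in design")
  gi <- match(design$hybrid, rownames(genotypes))
  if (anyNA(gi)) stop("unknown hybrid in design: ",
                      paste(utils::head(unique(design$hybrid[is.na(gi)]), 3),
                            collapse = ", "))
  loci <- names(truth$locus_effects)
  gsum <- if (length(loci) > 0) {
    as.numeric(genotypes[gi, loci, drop = FALSE] %*% truth$locus_effects)
  } else 0
  offs <- truth$treatment_offsets[design$treatment]
  offs[is.na(offs)] <- 0
  late <- pmax(0, design$planting_doy - truth$planting_window_end)
  y <- truth$baseline +
    truth$state_effects[design$state] +
    gsum + offs - truth$planting_penalty * late
  noise <- with_seed(seed, stats::rnorm(nrow(design), 0, truth$noise_sd))
  pmax(0, as.numeric(y + noise))
}

#' Generate a full six-table synthetic dataset
#'
#' Emits trait, metadata, daily weather (16 features), soil (23 features),
#' environmental (6 soil groups at 10 depths x 9 stages, a Flow group at
#' 9 x 9, and 4 phenology features at 9 stages), and genotype call strings,
#' plus the ground-truth record of every injected effect. Identical seeds
#' produce byte-identical tables.
#'
#' @param config A [synthetic_config()].
#' @return List of class `raw_dataset`: `trait`, `metadata`, `weather`,
#'   `soil`, `envsim`, `genotype_calls`, `truth`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  es <- config$effect_sizes
  with_seed(config$seed, {
    states <- paste0("ST", seq_len(config$n_states))
    locs <- paste0("LOC", seq_len(config$n_states * config$envs_per_state))
    loc_state <- rep(states, each = config$envs_per_state)
    hybrids <- default_hybrid_names(config$n_hybrids)

    envs <- expand.grid(location = locs, year = config$years,
                        stringsAsFactors = FALSE)
    envs$state <- loc_state[match(envs$location, locs)]
    envs$env <- paste(envs$location, envs$year, sep = "_")

    # ground truth
    state_effects <- stats::setNames(stats::rnorm(length(states), 0, es$state_sd),
                                     states)
    causal <- sample(paste0("L", seq_len(config$n_loci)),
                     min(es$n_causal_loci, config$n_loci))
    locus_effects <- stats::setNames(
      sample(c(-1, 1), length(causal), replace = TRUE) * es$locus_effect, causal)
    truth <- list(baseline = es$baseline, state_effects = state_effects,
                  locus_effects = locus_effects,
                  treatment_offsets = es$treatment_offsets,
                  planting_penalty = es$planting_penalty,
                  planting_window_end = es$planting_window_end,
                  noise_sd = es$noise_sd)

    # metadata: one treatment + planting date per Env
    n_env <- nrow(envs)
    tr_prob <- c(0.5, rep(0.5 / (length(config$treatment_classes) - 1),
                          length(config$treatment_classes) - 1))
    metadata <- data.frame(
      env = envs$env, location = envs$location, state = envs$state,
      year = envs$year,
      treatment = sample(config$treatment_classes, n_env, replace = TRUE,
                         prob = tr_prob),
      stringsAsFactors = FALSE
    )
    # planting day: in-window for most, past the window for late plantings
    base_doy <- round(stats::runif(n_env, 100, es$planting_window_end - 5))
    late <- metadata$treatment == "late planting"
    base_doy[late] <- round(stats::runif(sum(late), es$planting_window_end + 10,
                                         es$planting_window_end + 50))
    metadata$planting_date <- as.character(
      as.Date(paste0(metadata$year, "-01-01")) + (base_doy - 1))
    metadata$comment <- sample(
      c("", "deer damage at border", "storm lodging week 30",
        "sensor data gap", "dry spell in july", "nothing to report"),
      n_env, replace = TRUE, prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
    if (config$missing_rates$metadata > 0) {
      mi <- stats::runif(n_env) < config$missing_rates$metadata
      metadata$treatment[mi] <- NA
    }

    # genotype calls
    geno_hybrids <- hybrids
    if (config$genotype_coverage < 1)
      geno_hybrids <- sort(sample(hybrids,
                                  round(config$genotype_coverage *
                                          config$n_hybrids)))
    calls <- generate_genotype_calls(
      length(geno_hybrids), config$n_loci, config$call_mix,
      missing_rate = config$missing_rates$genotype,
      missing_marker = config$missing_marker,
      seed = sample.int(1e6, 1), hybrids = geno_hybrids)
    dosages <- encode_calls(calls, missing_markers = config$missing_marker)
    dos_complete <- dosages
    dos_complete[is.na(dos_complete)] <- 0  # truth uses observed dosage, NA ~ ref

    # trait rows: a fraction of hybrids per Env
    n_per_env <- max(1L, round(config$frac_hybrids_per_env * config$n_hybrids))
    design <- do.call(rbind, lapply(seq_len(n_env), function(i) {
      hy <- sample(geno_hybrids, min(n_per_env, length(geno_hybrids)))
      data.frame(env = envs$env[i], state = envs$state[i],
                 year = envs$year[i], hybrid = hy, stringsAsFactors = FALSE)
    }))
    md_i <- match(design$env, metadata$env)
    design$treatment <- metadata$treatment[md_i]
    design$treatment[is.na(design$treatment)] <- "standard"  # truth uses real class
    design$planting_doy <- planting_date_to_doy(metadata$planting_date[md_i])
    design$yield <- inject_yield(truth, design, dos_complete,
                                 seed = sample.int(1e6, 1))
    trait <- design[, c("env", "hybrid", "yield")]

    # daily weather: 16 features, seasonal sinusoid + env-specific level
    wf <- c("tmax", "tmin", "tmean", "dewpoint", "rh", "vpd", "srad", "par",
            "precip", "wind", "gust", "soilt", "soilm", "pressure", "et0", "gdd")
    doy <- seq_len(config$n_days)
    weather <- do.call(rbind, lapply(seq_len(n_env), function(i) {
      level <- stats::rnorm(16, 0, 1)
      season <- sin(2 * pi * (doy - 30) / 365)
      feats <- vapply(seq_len(16), function(f) {
        10 + 5 * season + level[f] + stats::rnorm(config$n_days, 0, 0.5)
      }, numeric(config$n_days))
      colnames(feats) <- wf
      data.frame(env = envs$env[i],
                 date = as.character(as.Date(paste0(envs$year[i], "-01-01")) +
                                       (doy - 1)),
                 feats, stringsAsFactors = FALSE)
    }))

    # soil: 23 features per Env, correlated within location
    sf <- paste0("soil_", sprintf("%02d", 1:23))
    loc_soil <- matrix(stats::rnorm(length(locs) * 23, 5, 2), nrow = length(locs),
                       dimnames = list(locs, sf))
    soil <- data.frame(env = envs$env, location = envs$location,
                       state = envs$state, year = envs$year,
                       loc_soil[envs$location, , drop = FALSE] +
                         matrix(stats::rnorm(n_env * 23, 0, 0.3), n_env),
                       stringsAsFactors = FALSE, row.names = NULL)
    if (config$missing_rates$soil > 0) {
      m <- matrix(stats::runif(n_env * 23) < config$missing_rates$soil, n_env)
      for (k in seq_len(23)) soil[[sf[k]]][m[, k]] <- NA
    }

    # environmental (APSIM-like): 6 soil groups 10x9, Flow 9x9, 4 pheno x 9.
    # Smooth random fields; the first group tracks the Env's state effect so
    # the block carries yield-relevant signal.
    groups <- c("SWSD", "ESW", "FlowUp", "NO3Leach", "SWC", "PAW")
    env_cols <- character(0)
    env_mat <- NULL
    smooth_field <- function(nr, nc, level) {
      base <- outer(seq_len(nr) / nr, seq_len(nc) / nc, function(a, b)
        sin(2 * pi * a) + cos(pi * b))
      level + base + matrix(stats::rnorm(nr * nc, 0, 0.2), nr)
    }
    env_rows <- lapply(seq_len(n_env), function(i) {
      st_eff <- state_effects[envs$state[i]]
      vals <- unlist(lapply(seq_along(groups), function(gidx) {
        lvl <- if (gidx == 1) st_eff else stats::rnorm(1, 0, 1)
        as.numeric(smooth_field(10, 9, lvl))
      }))
      flow <- as.numeric(smooth_field(9, 9, stats::rnorm(1, 0, 1)))
      pheno <- as.numeric(vapply(1:4, function(p)
        stats::rnorm(1, 0, 1) + sin(2 * pi * (1:9) / 9) +
          stats::rnorm(9, 0, 0.2), numeric(9)))
      c(vals, flow, pheno)
    })
    env_cols <- c(
      unlist(lapply(groups, function(g)
        paste0(g, "_d", rep(1:10, times = 9), "_s", rep(1:9, each = 10)))),
      paste0("Flow_d", rep(1:9, times = 9), "_s", rep(1:9, each = 9)),
      paste0(rep(c("GrainSim", "Biomass", "WaterTable", "LAI"), each = 9),
             "_s", 1:9))
    env_mat <- do.call(rbind, env_rows)
    colnames(env_mat) <- env_cols
    envsim <- data.frame(env = envs$env, location = envs$location,
                         state = envs$state, year = envs$year, env_mat,
                         stringsAsFactors = FALSE, row.names = NULL)
    if (config$missing_rates$envsim > 0) {
      m <- matrix(stats::runif(n_env * length(env_cols)) <
                    config$missing_rates$envsim, n_env)
      for (k in seq_along(env_cols)) envsim[[env_cols[k]]][m[, k]] <- NA
    }

    structure(list(trait = trait, metadata = metadata, weather = weather,
                   soil = soil, envsim = envsim, genotype_calls = calls,
                   truth = truth, config = config),
              class = "raw_dataset")
  })
}

#' Write the six tables of a synthetic dataset as CSV
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @param vcf Also write the genotype calls as a minimal VCF whose GT field
#'   carries the call strings (one pseudo-variant per locus).
#' @return Invisibly, the paths written.
#' @export
write_dataset_csv <- function(dataset, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("trait", "metadata", "weather", "soil", "envsim")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(dataset[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  gp <- file.path(dir, "genotype.csv")
  gdf <- data.frame(hybrid = rownames(dataset$genotype_calls),
                    dataset$genotype_calls, check.names = FALSE)
  utils::write.csv(gdf, gp, row.names = FALSE)
  paths <- c(paths, gp)
  if (vcf) {
    vp <- file.path(dir, "genotype.vcf")
    write_genotype_vcf(dataset$genotype_calls, vp)
    paths <- c(paths, vp)
  }
  invisible(paths)
}

# Minimal VCF writer: one row per locus on a pseudo-chromosome, GT = call.
write_genotype_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(calls)), collapse = "\t")),
             con)
  for (j in seq_len(ncol(calls))) {
    writeLines(paste(c("1", j, colnames(calls)[j], "A", "T", ".", "PASS", ".",
                       "GT", calls[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype call strings from a minimal VCF (GT field only)
#'
#' @param path VCF path.
#' @return Character matrix hybrids x loci.
#' @export
read_genotype_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) stop("no #CHROM header line in ", path)
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  rows <- strsplit(body, "\t")
  ids <- vapply(rows, `[`, "", 3)
  mat <- matrix(unlist(lapply(rows, function(r) r[-(1:9)])),
                nrow = length(samples), dimnames = list(samples, ids))
  mat
}
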