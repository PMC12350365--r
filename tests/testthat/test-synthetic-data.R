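test_that("generated tables have the declared shapes and keys", {
  fx <- make_tiny_prep()
  raw <- fx$raw
  expect_named(raw$trait, c("env", "hybrid", "yield"))
  expect_true(all(c("env", "treatment", "planting_date") %in%
                    names(raw$metadata)))
  # 16 weather features beyond the env/date keys
  expect_length(setdiff(names(raw$weather), c("env", "date")), 16)
  expect_length(grep("^soil_", names(raw$soil)), 23)
  expect_equal(dim(raw$genotype_calls), c(24, 200))
  # every trait Env appears in the metadata
  expect_true(all(raw$trait$env %in% raw$metadata$env))
  # Env keys are location_year
  pe <- parse_env(raw$metadata$env)
  expect_true(all(pe$year %in% 2018:2021))
  # envsim: 6 groups at 10x9, Flow at 9x9, 4 phenology features at 9 stages
  env_cols <- setdiff(names(raw$envsim), c("env", "location", "state", "year"))
  expect_length(env_cols, 6 * 90 + 81 + 36)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_synth_config(seed = 9L)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  # different seed changes the data
  other <- generate_dataset(tiny_synth_config(seed = 10L))
  expect_false(identical(generate_dataset(cfg)$trait$yield,
                         other$trait$yield))
})

test_that("missing-rate targets are met within tolerance", {
  raw <- generate_dataset(tiny_synth_config(
    seed = 3L, missing_rates = list(metadata = 0, soil = 0.2, envsim = 0,
                                    genotype = 0)))
  soil_cells <- as.matrix(raw$soil[, grep("^soil_", names(raw$soil))])
  expect_lt(abs(mean(is.na(soil_cells)) - 0.2), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_states = 0), "counts")
  expect_error(synthetic_config(missing_rates = list(metadata = 1.2, soil = 0,
                                                     envsim = 0, genotype = 0)),
               "missing_rates")
  expect_error(synthetic_config(
    effect_sizes = modifyList(synthetic_config()$effect_sizes,
                              list(noise_sd = -1))), "noise")
})

test_that("genotype call generator respects mix, missingness and bounds", {
  calls <- generate_genotype_calls(20, 50, missing_rate = 0, seed = 1)
  expect_equal(dim(calls), c(20, 50))
  expect_false(any(calls == "./."))
  # rare-call mass stays below 5% under the default mix
  big <- generate_genotype_calls(200, 500, missing_rate = 0, seed = 2)
  rare <- mean(!big %in% c("0/0", "0/1", "1/0", "1/1"))
  expect_lt(rare, 0.05)
  expect_error(generate_genotype_calls(5, 5, call_mix = c(`0/0` = -0.5,
                                                          `1/1` = 1.5)),
               "nonnegative")
})

test_that("heavily missing loci are removed downstream by the locus filter", {
  calls <- generate_genotype_calls(30, 40, missing_rate = 0, seed = 4)
  drop_loci <- paste0("L", 1:10)
  for (l in drop_loci) {
    mask <- withr::with_seed(5, sample(30, 27))  # 90% missing
    calls[mask, l] <- "./."
  }
  enc <- encode_calls(calls)
  kept <- drop_missing_loci(enc, policy = "fraction", threshold = 0.8)
  expect_true(all(attr(kept, "removed")$locus %in% drop_loci))
  expect_setequal(attr(kept, "removed")$locus, drop_loci)
})

test_that("inject_yield reproduces the additive truth exactly at zero noise", {
  geno <- matrix(c(0, 0.5, 1, 0.5), 2, 2,
                 dimnames = list(c("A/B", "C/D"), c("L1", "L2")))
  truth <- list(baseline = 9.44,
                state_effects = c(ST1 = 0),
                locus_effects = numeric(0),
                treatment_offsets = c(standard = 0),
                planting_penalty = 0, planting_window_end = 140, noise_sd = 0)
  design <- data.frame(state = "ST1", hybrid = c("A/B", "C/D"),
                       treatment = "standard", planting_doy = c(120, 130))
  expect_equal(inject_yield(truth, design, geno), c(9.44, 9.44))

  # late planting 40 days past the window at 0.05 Mg/ha/day costs exactly 2.0
  truth$planting_penalty <- 0.05
  twin <- data.frame(state = "ST1", hybrid = "A/B", treatment = "standard",
                     planting_doy = c(130, 180))
  y <- inject_yield(truth, twin, geno)
  expect_equal(y[1] - y[2], 2.0)

  expect_error(inject_yield(truth, data.frame(state = "XX", hybrid = "A/B",
                                              treatment = "standard",
                                              planting_doy = 120), geno),
               "unknown state")
})

test_that("OLS on generated data recovers an injected locus effect within 2 SE", {
  n <- 400
  geno <- matrix(withr::with_seed(1, sample(c(0, 0.5, 1), n * 1, TRUE)),
                 ncol = 1, dimnames = list(paste0("H", 1:n), "L1"))
  truth <- list(baseline = 9, state_effects = c(ST1 = 0),
                locus_effects = c(L1 = 0.6),
                treatment_offsets = c(standard = 0),
                planting_penalty = 0, planting_window_end = 140, noise_sd = 1)
  design <- data.frame(state = "ST1", hybrid = paste0("H", 1:n),
                       treatment = "standard", planting_doy = 120)
  y <- inject_yield(truth, design, geno, seed = 8)
  fit <- summary(lm(y ~ geno[, 1]))
  est <- fit$coefficients[2, "Estimate"]
  se <- fit$coefficients[2, "Std. Error"]
  expect_lt(abs(est - 0.6), 2 * se)
})

test_that("yields are nonnegative/finite and zero-noise state means are exact", {
  es <- synthetic_config()$effect_sizes
  es$noise_sd <- 0
  es$locus_effect <- 0
  es$planting_penalty <- 0
  es$treatment_offsets[] <- 0
  raw <- generate_dataset(tiny_synth_config(seed = 6L, effect_sizes = es))
  expect_true(all(is.finite(raw$trait$yield)))
  expect_true(all(raw$trait$yield >= 0))
  st <- raw$metadata$state[match(raw$trait$env, raw$metadata$env)]
  means <- tapply(raw$trait$yield, st, mean)
  expected <- raw$truth$baseline + raw$truth$state_effects[names(means)]
  expect_equal(as.numeric(means), as.numeric(expected))
})

test_that("CSV and VCF round trips preserve the tables", {
  fx <- make_tiny_prep()
  d <- withr::local_tempdir()
  write_dataset_csv(fx$raw, d, vcf = TRUE)
  back <- read_dataset_csv(d)
  expect_equal(back$trait$yield, fx$raw$trait$yield)
  expect_equal(dim(back$genotype_calls), dim(fx$raw$genotype_calls))
  vcf_calls <- read_genotype_vcf(file.path(d, "genotype.vcf"))
  expect_identical(unname(vcf_calls), unname(fx$raw$genotype_calls))
})
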