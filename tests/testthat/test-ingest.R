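test_that("treatment mode imputation fills missing values deterministically", {
  md <- data.frame(treatment = c("standard", "standard", "drought", NA))
  expect_equal(impute_metadata(md)$treatment[4], "standard")
  # no missing values: unchanged
  md2 <- data.frame(treatment = c("drought", "standard"))
  expect_identical(impute_metadata(md2), md2)
  # tie broken lexicographically
  md3 <- data.frame(treatment = c("drought", "drought", "standard",
                                  "standard", NA))
  expect_equal(impute_metadata(md3)$treatment[5], "drought")
  expect_error(impute_metadata(data.frame(treatment = c(NA, NA))),
               "entirely missing")
})

test_that("planting dates convert to 1-based day of year with leap years", {
  expect_identical(planting_date_to_doy("2021-01-01"), 1L)
  expect_identical(planting_date_to_doy("2021-04-15"), 105L)
  expect_identical(planting_date_to_doy("2020-03-01"), 61L)  # leap year
  expect_error(planting_date_to_doy("not-a-date"), "unparseable")
})

test_that("issue comments map onto the six categories", {
  cls <- classify_issues(c(NA, "", "deer damage", "sensor data gap",
                           "dry spell", "hail storm", "odd remark"))
  expect_equal(cls, c("no issues", "no issues", "animal attack",
                      "data issues", "drought", "storm", "miscellaneous"))
})

make_daily <- function(values, n_days = 365, env = "L1_2021") {
  data.frame(env = env,
             date = as.character(as.Date("2021-01-01") + seq_len(n_days) - 1),
             f1 = values)
}

test_that("weekly aggregation covers 48 weeks and drops late days", {
  wk <- weather_to_weekly(make_daily(rep(3.5, 365)))
  expect_equal(dim(wk[["L1_2021"]]), c(48, 1))
  expect_true(all(wk[["L1_2021"]] == 3.5))
  # week 1 mean of days 1..7 = 1..7 is 4
  v <- rep(0, 365); v[1:7] <- 1:7
  wk2 <- weather_to_weekly(make_daily(v))
  expect_equal(wk2[["L1_2021"]][1, 1], 4.0)
  # day 337 onward does not influence any week
  v3 <- rep(1, 365); v3[337:365] <- 1000
  wk3 <- weather_to_weekly(make_daily(v3))
  expect_true(all(wk3[["L1_2021"]] == 1))
})

test_that("weekly aggregation rejects short coverage and wrong cadence", {
  expect_error(weather_to_weekly(make_daily(rnorm(200), n_days = 200)),
               "L1_2021")
  # already-weekly data (48 rows) is a coverage error, not silently re-aggregated
  wk48 <- data.frame(env = "L1_2021",
                     date = as.character(as.Date("2021-01-01") + (0:47) * 7),
                     f1 = rnorm(48))
  expect_error(weather_to_weekly(wk48), "coverage")
})

test_that("per-feature aggregator overrides apply", {
  daily <- make_daily(rep(2, 365))
  daily$f2 <- 1
  wk <- weather_to_weekly(daily, aggregator = c(f2 = "sum"))
  expect_equal(wk[["L1_2021"]][1, "f1"], 2)   # default mean
  expect_equal(wk[["L1_2021"]][1, "f2"], 7)   # weekly sum
})

hier_table <- function() {
  data.frame(location = rep(c("L1", "L2"), each = 3),
             state = "S1", year = rep(2014:2016, 2),
             x = c(NA, 5, 7, 4, 4, 4))
}

test_that("location-then-state imputation hierarchy fills in order", {
  out <- impute_by_location_hierarchy(hier_table(), "x")
  expect_equal(out$x[1], 6)  # mean of the same location's other years
  log <- attr(out, "imputation_log")
  expect_equal(log$pass1, 1L)
  # location entirely missing -> state mean
  tb <- hier_table()
  tb$x[1:3] <- NA
  out2 <- impute_by_location_hierarchy(tb, "x")
  expect_equal(out2$x[1:3], rep(4, 3))
  expect_equal(attr(out2, "imputation_log")$pass2, 3L)
  # nothing missing: unchanged
  tb3 <- hier_table(); tb3$x[1] <- 9
  expect_equal(impute_by_location_hierarchy(tb3, "x")$x, tb3$x)
})

test_that("imputation never alters non-missing cells", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      tb <- data.frame(location = sample(c("L1", "L2", "L3"), 30, TRUE),
                       state = sample(c("S1", "S2"), 30, TRUE),
                       year = sample(2014:2018, 30, TRUE),
                       a = rnorm(30), b = rnorm(30))
      miss <- sample(30, 8)
      tb$a[miss] <- NA
      out <- impute_by_location_hierarchy(tb, c("a", "b"))
      expect_identical(out$a[-miss], tb$a[-miss])
      expect_identical(out$b, tb$b)
    }
  })
})

test_that("state-level gaps survive both passes with a warning and flag", {
  tb <- data.frame(location = c("L1", "L2"), state = "S1",
                   year = c(2014, 2015), x = c(NA, NA))
  expect_warning(out <- impute_by_location_hierarchy(tb, "x"),
                 "entirely missing")
  expect_true(all(attr(out, "row_flagged")))
})

test_that("join_all resolves keys, flags missing genotypes, and is order-independent", {
  fx <- make_tiny_prep()
  m <- fx$prep$merged
  expect_equal(nrow(m$frame), nrow(fx$raw$trait))
  expect_equal(dim(m$weather)[2:3], c(48, 16))
  expect_false(any(is.na(m$weather)))
  # join is independent of trait row order
  raw <- fx$raw
  perm <- withr::with_seed(2, sample(nrow(raw$trait)))
  raw$trait <- raw$trait[perm, ]
  m2 <- preprocess_dataset(raw, locus_filter_params(n_sample = 15, seed = 2))$merged
  expect_equal(m2$frame$yield, m$frame$yield)
})

test_that("trait rows whose hybrid lacks genotype are flagged, not dropped", {
  fx <- make_tiny_prep()
  raw <- fx$raw
  raw$trait$hybrid[1:5] <- "GHOST/HYBRID"
  prep <- preprocess_dataset(raw, locus_filter_params(n_sample = 15, seed = 2))
  expect_equal(sum(prep$merged$frame$genotype_missing), 5L)
  expect_equal(nrow(prep$merged$frame), nrow(raw$trait))
})

test_that("degenerate joins behave: empty trait ok, duplicate Env keys error", {
  fx <- make_tiny_prep()
  raw <- fx$raw
  raw$trait <- raw$trait[0, ]
  prep <- preprocess_dataset(raw, locus_filter_params(n_sample = 15, seed = 2))
  expect_equal(nrow(prep$merged$frame), 0L)

  raw2 <- fx$raw
  raw2$soil <- rbind(raw2$soil, raw2$soil[1, ])
  expect_error(preprocess_dataset(raw2, locus_filter_params(n_sample = 15,
                                                            seed = 2)),
               "duplicate Env")
})
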