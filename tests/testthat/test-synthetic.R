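test_that("range-calibrated DFS curves hit their monthly probability bounds", {
  for (rng in list(c(0.0002, 0.0035), c(0.0014, 0.0088), c(0.0021, 0.0284))) {
    curve <- make_dfs_curve(rng[1], rng[2], support = 60)
    p <- curve_to_monthly_probs(curve)
    expect_length(p, 60L)
    expect_equal(min(p), rng[1], tolerance = 1e-9)
    expect_equal(max(p), rng[2], tolerance = 1e-9)
    # rising-hazard Weibull: monotone increasing within the bounds
    expect_true(all(diff(p) > -1e-15))
  }

  # degenerate range collapses to a constant hazard at the bound
  cst <- curve_to_monthly_probs(make_dfs_curve(0.0035, 0.0035, support = 60))
  expect_equal(cst, rep(0.0035, 60), tolerance = 1e-12)

  # survival reconstruction reproduces S(60) exactly
  curve <- make_dfs_curve(0.0014, 0.0088, support = 60)
  p <- curve_to_monthly_probs(curve)
  expect_equal(prod(1 - p), curve$survival[61], tolerance = 1e-9)
})

test_that("5-year-survival-targeted curves meet the target or report infeasibility", {
  curve <- make_dfs_curve(0.0002, 0.0088, support = 60,
                          target_5yr_survival = 0.70)
  expect_equal(curve$survival[61], 0.70, tolerance = 1e-6)
  p <- curve_to_monthly_probs(curve)
  expect_lte(max(p), 0.0088 + 1e-9)
  expect_gte(min(p), 0.0002 - 1e-9)

  # a target inconsistent with the requested range names the attainable one
  expect_error(make_dfs_curve(0.005, 0.0088, support = 60,
                              target_5yr_survival = 0.95),
               "attainable")
  expect_error(make_dfs_curve(0.005, 0.0284, support = 60,
                              target_5yr_survival = 0.70),
               "attainable")
})

test_that("post-recurrence strata honour the median and the hazard ratio", {
  pr <- make_post_recurrence_curves(median_doublet = 24, hr_single_or_none = 1.61)
  expect_equal(pr$doublet$survival[25], 0.5, tolerance = 1e-9)
  # the hazard-adjusted stratum has uniformly lower survival
  expect_true(all(pr$single_or_none$survival[-1] < pr$doublet$survival[-1]))

  same <- make_post_recurrence_curves(median_doublet = 24, hr_single_or_none = 1)
  expect_equal(same$single_or_none$survival, same$doublet$survival,
               tolerance = 1e-12)
})

test_that("the fixture life table yields non-decreasing background mortality", {
  lt <- make_life_table()
  p <- life_table_to_monthly(lt, 60, 300)
  expect_true(all(diff(p) >= 0))

  flat <- make_life_table(seq(40, 85, 5), rep(0.02, 10))
  expect_equal(unique(life_table_to_monthly(flat, 60, 300)),
               1 - 0.98^(1 / 12), tolerance = 1e-12)

  # zero background mortality: survival is bounded by the horizon alone
  none <- make_life_table(seq(40, 85, 5), rep(0, 10))
  cfg <- make_full_config("HIGH_RISK_II")
  cfg$life_table <- none
  tr <- run_strategy(cfg, "no_adjuvant")$trace
  expect_equal(unname(tr$occupancy[301, "DEAD_OTHER"]), 0)
})

test_that("generated configurations are complete, range-true and deterministic", {
  for (stage in c("HIGH_RISK_II", "III")) {
    cfg <- make_full_config(stage)
    ranges <- coloncea:::.recurrence_ranges[[stage]]
    for (k in names(cfg$strategies)) {
      p <- cfg$strategies[[k]]$p_recur
      expect_gte(min(p), ranges[[k]][1] - 1e-12)
      expect_lte(max(p), ranges[[k]][2] + 1e-12)
      # loader validation: the full pipeline runs on the generated inputs
      expect_s3_class(run_strategy(cfg, k)$trace, "cohort_trace")
    }
    # qualitative structure: 5-year disease-free survival orders the arms
    s60 <- vapply(cfg$strategies,
                  function(s) prod(1 - s$p_recur), numeric(1))
    expect_lt(s60[["no_adjuvant"]], s60[["cape6"]])
    expect_lt(s60[["cape6"]], min(s60[["capox3"]], s60[["capox6"]]))
  }
  expect_identical(make_full_config("III", seed = 7),
                   make_full_config("III", seed = 7))
})

test_that("configuration directories round-trip and write byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- make_full_config("III")
  write_config_dir(cfg, dir1)
  write_config_dir(cfg, dir2)

  files <- list.files(dir1, recursive = TRUE)
  expect_setequal(files, list.files(dir2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6),
                     label = sprintf("%s byte-identical", f))
  }

  back <- read_config_dir(dir1)
  bc0 <- run_base_case(cfg)
  bc1 <- run_base_case(back)
  expect_equal(bc1$cost, bc0$cost, tolerance = 1e-6)
  expect_equal(bc1$daly, bc0$daly, tolerance = 1e-6)
  expect_identical(bc1$dominance, bc0$dominance)
})
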