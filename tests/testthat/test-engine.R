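settings300 <- model_settings() # start 60, max 85 -> 300 cycles

test_that("degenerate schedules behave as identities", {
  # no events at all: the cohort never leaves the disease-free state
  sched <- transition_schedules(rep(0, 300), rep(0, 300), rep(0, 300))
  tr <- run_cohort(settings300, null_strategy(), sched)
  expect_equal(tr$occupancy[, "DISEASE_FREE"], rep(1, 301))
  expect_equal(overall_survival_years(tr), 25)

  # certain background death in the first cycle collapses into DEAD_OTHER
  pdo <- c(1, rep(0, 299))
  tr2 <- run_cohort(settings300, null_strategy(),
                    transition_schedules(rep(0, 300), rep(0, 300), pdo))
  expect_equal(tr2$occupancy[-1L, "DEAD_OTHER"], rep(1, 300))
  expect_equal(overall_survival_years(tr2), 0.5 / 12) # half a cycle alive
})

test_that("occupancy is conserved and absorbing states are monotone", {
  set.seed(83)
  for (i in 1:15) {
    h <- 60L
    s <- model_settings(start_age = 80, horizon = h)
    sched <- transition_schedules(runif(h, 0, 0.05), runif(h, 0, 0.2),
                                  runif(h, 0, 0.02))
    strat <- null_strategy(dur = 0L)
    strat$first_line$duration <- sample(1:12, 1)
    strat$second_line$duration <- sample(0:12, 1)
    tr <- run_cohort(s, strat, sched)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1 + 1e-12))
    expect_true(all(diff(tr$occupancy[, "DEAD_CC"]) >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "DEAD_OTHER"]) >= -1e-15))
  }
})

test_that("cohort trace matches an independent microsimulation oracle", {
  # constant-probability instance; individual-level simulation of 50,000
  # patients must agree with the deterministic trace within 3 SE
  set.seed(20260921)
  n <- 50000L
  ms <- oracle_microsim(n, 300L, p_recur = 0.01, p_dcc = 0.05, p_do = 0.002)
  sched <- transition_schedules(rep(0.01, 300), rep(0.05, 300), rep(0.002, 300))
  tr <- run_cohort(settings300, null_strategy(), sched)
  for (cyc in c(12L, 60L, 120L, 300L)) {
    o <- tr$occupancy[cyc + 1L, ]
    agg <- c(o[1L], sum(o[2:4]), o[5L], o[6L])
    m <- ms[cyc, ]
    se <- sqrt(pmax(m * (1 - m), 1e-12) / n)
    expect_true(all(abs(agg - m) <= 3 * pmax(se, 1e-9)),
                label = sprintf("cycle %d within 3 SE of microsimulation", cyc))
  }
})

test_that("overall survival matches the geometric closed form", {
  q <- 0.01
  sched <- transition_schedules(rep(0, 300), rep(0, 300), rep(q, 300))
  tr <- run_cohort(settings300, null_strategy(), sched)
  s <- 1 - q
  # trapezoidal life years of a geometric lifetime truncated at the horizon
  expected <- (1 + s) / 2 * (1 - s^300) / (1 - s) / 12
  expect_equal(overall_survival_years(tr), expected, tolerance = 1e-9)

  # a cohort dead from the outset accrues nothing
  occ <- matrix(0, 13, 6)
  occ[, 5] <- 1
  expect_equal(overall_survival_years(fake_trace(occ)), 0)
})

test_that("raising any recurrence probability never increases survival", {
  set.seed(51)
  h <- 120L
  s <- model_settings(start_age = 75, horizon = h)
  base_p <- runif(h, 0, 0.02)
  sched <- transition_schedules(base_p, rep(0.08, h), rep(0.003, h))
  os0 <- overall_survival_years(run_cohort(s, null_strategy(), sched))
  for (i in 1:10) {
    p2 <- base_p
    j <- sample(h, 1)
    p2[j] <- min(1, p2[j] + runif(1, 0.01, 0.3))
    os1 <- overall_survival_years(
      run_cohort(s, null_strategy(), transition_schedules(p2, rep(0.08, h), rep(0.003, h)))
    )
    expect_lte(os1, os0 + 1e-12)
  }
})

test_that("post-recurrence mortality is indexed by months since recurrence", {
  h <- 20L
  s <- model_settings(start_age = 80, horizon = h)
  # everyone recurs during cycle 0; certain cancer death at tunnel month 2
  p_recur <- c(1, rep(0, h - 1L))
  pdc <- rep(0, h)
  pdc[3L] <- 1 # months_since_recurrence = 2
  tr <- run_cohort(s, null_strategy(), transition_schedules(p_recur, pdc, rep(0, h)))
  # recurrence entered at boundary 1 (m = 0); m = 2 is lived during cycle 4
  expect_equal(unname(tr$occupancy[4L, "DEAD_CC"]), 0)
  expect_equal(unname(tr$occupancy[5L, "DEAD_CC"]), 1)
})

test_that("recurrence entries split across pathways and treatment lines", {
  h <- 30L
  s <- model_settings(start_age = 80, horizon = h)
  strat <- null_strategy()
  strat$first_line$duration <- 6L
  p_recur <- c(1, rep(0, h - 1L))
  tr <- run_cohort(s, strat, transition_schedules(p_recur, rep(0, h), rep(0, h)))
  expect_equal(unname(tr$occupancy[2L, "REC_HEPATECTOMY"]), 1 / 9, tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[2L, "REC_FIRST_LINE"]), 8 / 9, tolerance = 1e-12)
  # the whole chemotherapy pathway reaches second line after 6 months
  expect_equal(unname(tr$occupancy[8L, "REC_FIRST_LINE"]), 0, tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[8L, "REC_SECOND_LINE"]), 8 / 9, tolerance = 1e-12)
  expect_equal(sum(tr$flows$new_second_line), 8 / 9, tolerance = 1e-12)
})

test_that("schedules shorter than the horizon fail loudly except recurrence", {
  h <- 50L
  s <- model_settings(start_age = 80, horizon = h)
  expect_error(
    run_cohort(s, null_strategy(),
               transition_schedules(rep(0, h), rep(0.1, 10), rep(0, h))),
    "p_death_cc.*deficit 40"
  )
  expect_error(
    run_cohort(s, null_strategy(),
               transition_schedules(rep(0, h), rep(0.1, h), rep(0.01, 10))),
    "p_death_other.*deficit 40"
  )
  # recurrence risk beyond its support is exhausted, not an error
  tr <- run_cohort(s, null_strategy(),
                   transition_schedules(rep(0.01, 10), rep(0.1, h), rep(0, h)))
  expect_equal(unname(tr$occupancy[11L, "DISEASE_FREE"]),
               unname(tr$occupancy[h + 1L, "DISEASE_FREE"]), tolerance = 1e-12)
  expect_error(transition_schedules(c(0.5, 1.2), rep(0, 5), rep(0, 5)), "\\[0, 1\\]")
})

test_that("model DFS round-trips its calibration curve", {
  lam <- 0.008
  curve <- survival_curve(0:120, exp(-lam * (0:120)), label = "exp")
  p <- curve_to_monthly_probs(curve)
  h <- 120L
  s <- model_settings(start_age = 75, horizon = h)

  # no background mortality: exact identity
  tr <- run_cohort(s, null_strategy(), transition_schedules(p, rep(0.05, h), rep(0, h)))
  expect_lt(validate_dfs(tr, curve), 1e-6)

  # with background mortality the adjusted denominator keeps the round trip
  pdo <- life_table_to_monthly(make_life_table(), 75, h)
  tr2 <- run_cohort(s, null_strategy(), transition_schedules(p, rep(0.05, h), pdo))
  expect_lt(validate_dfs(tr2, curve), 1e-9)

  # a perturbed schedule must validate strictly worse than the derived one
  p3 <- p
  p3[12] <- p3[12] * 1.5
  tr3 <- run_cohort(s, null_strategy(), transition_schedules(p3, rep(0.05, h), pdo))
  expect_gt(validate_dfs(tr3, curve), validate_dfs(tr2, curve))

  short <- survival_curve(0:48, exp(-lam * (0:48)))
  expect_error(validate_dfs(tr2, short), "48")
})
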