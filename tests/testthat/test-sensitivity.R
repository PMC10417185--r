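test_that("parameter distributions match their moment specifications", {
  set.seed(100)
  fx <- dist_spec("x", "FIXED", base = 0.3)
  expect_equal(sample_parameter(fx, 5), rep(0.3, 5))

  b <- dist_spec("x", "BETA", base = 0.3, sd_fraction = 0.10)
  xb <- sample_parameter(b, 1e5)
  expect_equal(mean(xb), 0.3, tolerance = 0.001 / 0.3)
  expect_equal(sd(xb), 0.03, tolerance = 0.002 / 0.03)
  expect_true(all(xb > 0 & xb < 1))

  g <- dist_spec("x", "GAMMA", base = 1200, sd_fraction = 0.25)
  xg <- sample_parameter(g, 1e5)
  expect_equal(mean(xg), 1200, tolerance = 0.005)
  expect_equal(sd(xg), 300, tolerance = 0.01)

  p <- dist_spec("x", "PERT", base = 0.451, min = 0.307, max = 0.600)
  xp <- sample_parameter(p, 1e5)
  expect_true(all(xp >= 0.307 & xp <= 0.600))
  expect_equal(mean(xp), (0.307 + 4 * 0.451 + 0.600) / 6, tolerance = 0.005)

  # infeasible moment matching is a configuration-time error
  expect_error(dist_spec("x", "BETA", base = 0.9, sd_fraction = 0.5),
               "infeasible")
  expect_error(dist_spec("x", "PERT", base = 0.2, min = 0.3, max = 0.6),
               "min <= base <= max")
})

cfg2 <- make_full_config("HIGH_RISK_II")
cfg3 <- make_full_config("III")

test_that("parameter perturbation is exact at the identity and errors on bad paths", {
  same <- perturb_config(cfg2, "p_recurrence", 1)
  expect_equal(same$strategies$capox3$p_recur, cfg2$strategies$capox3$p_recur)
  up <- perturb_config(cfg2, "p_recurrence", 1.25)
  expect_true(all(up$strategies$capox3$p_recur >= cfg2$strategies$capox3$p_recur))
  expect_error(perturb_config(cfg2, "no_such_thing", 1), "cannot resolve")
  expect_error(perturb_config(cfg2, "cost_adjuvant", 1, strategy = "bogus"),
               "unknown strategy")
})

test_that("one-way sensitivity collapses at the base value and is monotone in cost", {
  cmp <- c("capox3", "no_adjuvant")
  at_base <- one_way_dsa(cfg2, "p_recurrence", 1, 1, cmp)
  expect_equal(at_base$icer_low, at_base$icer_high)
  expect_equal(at_base$spread, 0)

  # raising only the intervention's adjuvant cost raises its ICER
  sweep <- one_way_dsa(cfg2, "cost_adjuvant", 0.5, 2, cmp, strategy = "capox3")
  expect_lt(sweep$icer_low, sweep$icer_high)
})

test_that("the widest tornado bar is the CAPOX 6-month adjuvant drug cost", {
  tor <- run_tornado(cfg2, c("capox6", "capox3"))
  expect_equal(tor$parameter[1], "cost_adjuvant:capox6")
  expect_true(all(diff(tor$spread) <= 1e-9))
})

test_that("threshold search recovers known crossings and reports absent ones", {
  cmp <- c("capox3", "no_adjuvant")
  base_icer <- coloncea:::.icer_pair(cfg2, cmp)
  at_base <- threshold_multiplier(cfg2, "cost_adjuvant", cmp, wtp = base_icer,
                                  strategy = "capox3")
  expect_equal(at_base$multiplier, 1, tolerance = 1e-3)

  # the ICER is linear in a pure cost multiplier: the root must match the
  # closed-form linear crossing computed from two evaluations
  m1 <- 0.5
  m2 <- 2.5
  i1 <- coloncea:::.icer_pair(perturb_config(cfg2, "cost_adjuvant", m1, "capox3"), cmp)
  i2 <- coloncea:::.icer_pair(perturb_config(cfg2, "cost_adjuvant", m2, "capox3"), cmp)
  wtp <- (i1 + i2) / 2 # guarantees a crossing inside the interval
  m_star <- m1 + (wtp - i1) * (m2 - m1) / (i2 - i1)
  th <- threshold_multiplier(cfg2, "cost_adjuvant", cmp, wtp = wtp,
                             interval = c(m1, m2), strategy = "capox3")
  expect_equal(th$multiplier, m_star, tolerance = 1e-3)

  none <- threshold_multiplier(cfg2, "cost_adjuvant", cmp, wtp = 1e9,
                               strategy = "capox3")
  expect_identical(none$status, "no threshold")
  expect_true(is.na(none$multiplier))
})

test_that("PSA with degenerate distributions reproduces the base case", {
  fixed <- lapply(psa_distributions(cfg3), function(d) {
    dist_spec(d$parameter, "FIXED", base = d$base, strategy = d$strategy,
              mode = d$mode)
  })
  p <- run_psa(cfg3, n_iterations = 3, seed = 1, distributions = fixed)
  bc <- run_base_case(cfg3)
  for (k in unique(p$draws$strategy)) {
    expect_equal(unique(p$draws$cost[p$draws$strategy == k]),
                 bc$cost[bc$strategy == k], tolerance = 1e-12)
  }
  # a degenerate CEAC is a step function: one strategy holds probability 1
  expect_true(all(p$ceac$probability_optimal %in% c(0, 1)))
})

test_that("PSA is seed-reproducible, conserves CEAC mass and matches the deterministic recommendation", {
  p1 <- run_psa(cfg3, n_iterations = 120, seed = 42)
  p2 <- run_psa(cfg3, n_iterations = 120, seed = 42)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)

  sums <- tapply(p1$ceac$probability_optimal, p1$ceac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  modal <- p1$optimal_base$strategy[which.max(p1$optimal_base$probability_optimal)]
  expect_equal(modal, recommended_strategy(run_base_case(cfg3)))
  expect_equal(p1$n_rejected, 0L)
})

test_that("subgroup re-parameterisation scales hazards and flips the optimum in high-risk disease", {
  unit <- subgroup_model(cfg3, multipliers = 1)
  expect_equal(unit$strategies$capox3$p_recur, cfg3$strategies$capox3$p_recur)

  up <- subgroup_model(cfg3, multipliers = 1.5)
  for (k in names(cfg3$strategies)) {
    expect_true(all(up$strategies[[k]]$p_recur >= cfg3$strategies[[k]]$p_recur))
  }
  expect_error(subgroup_model(cfg3, multipliers = -1), "positive")

  # high-recurrence-risk subgroups escalate to 6 months of doublet therapy
  expect_equal(recommended_strategy(run_base_case(subgroup_model(cfg3, "T4_or_N2"))),
               "capox6")
  expect_equal(recommended_strategy(run_base_case(subgroup_model(cfg2, "T4"))),
               "capox6")
  # low-risk subgroups retain the 3-month doublet course
  expect_equal(recommended_strategy(run_base_case(subgroup_model(cfg3, "T3N1"))),
               "capox3")
  expect_equal(recommended_strategy(run_base_case(subgroup_model(cfg2, "T3"))),
               "capox3")
})

test_that("the capecitabine-only scenario swaps FOLFIRI lines and nothing else", {
  sc <- scenario_xeliri(cfg3)
  for (k in names(cfg3$strategies)) {
    for (line in c("first_line", "second_line")) {
      old <- cfg3$strategies[[k]][[line]]
      new <- sc$strategies[[k]][[line]]
      if (old$regimen == "FOLFIRI") {
        expect_equal(new$regimen, "XELIRI")
        expect_equal(new$cost_zar, unname(cfg3$regimen_costs_zar[["XELIRI"]]))
      } else {
        expect_identical(new, old)
      }
    }
    s_old <- cfg3$strategies[[k]]
    s_new <- sc$strategies[[k]]
    s_old$first_line <- s_old$second_line <- NULL
    s_new$first_line <- s_new$second_line <- NULL
    expect_identical(s_new, s_old)
  }
  # idempotent: a configuration without FOLFIRI lines is unchanged
  expect_identical(scenario_xeliri(sc), sc)
  # the 3-month doublet course stays optimal under the scenario
  expect_equal(recommended_strategy(run_base_case(sc)), "capox3")
  expect_equal(recommended_strategy(run_base_case(scenario_xeliri(cfg2))), "capox3")
})
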