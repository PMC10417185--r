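# Shared test helpers: an independent individual-level microsimulation used
# as the engine oracle, a minimal trace builder for arithmetic checks, and a
# cost-free strategy stub.

# Event-by-event microsimulation of the cohort model with constant
# transition probabilities. Deliberately independent of the engine: it
# tracks individuals, draws uniforms per transition, and applies the same
# within-cycle convention (background death first, then recurrence from
# disease-free / cancer death from established recurrence; new recurrences
# are not at risk of death until the next cycle).
# Returns state fractions (DF, REC, DEAD_CC, DEAD_OTHER) after each cycle.
oracle_microsim <- function(n, h, p_recur, p_dcc, p_do) {
  state <- rep.int(1L, n) # 1 DF, 2 REC, 3 DEAD_CC, 4 DEAD_OTHER
  snap <- matrix(NA_real_, h, 4L)
  for (t in seq_len(h)) {
    rec_idx <- which(state == 2L)
    df_idx <- which(state == 1L)
    if (length(df_idx)) {
      die_o <- stats::runif(length(df_idx)) < p_do
      state[df_idx[die_o]] <- 4L
      alive <- df_idx[!die_o]
      state[alive[stats::runif(length(alive)) < p_recur]] <- 2L
    }
    if (length(rec_idx)) {
      die_o <- stats::runif(length(rec_idx)) < p_do
      state[rec_idx[die_o]] <- 4L
      alive <- rec_idx[!die_o]
      state[alive[stats::runif(length(alive)) < p_dcc]] <- 3L
    }
    snap[t, ] <- tabulate(state, 4L) / n
  }
  snap
}

# Strategy stub with no treatment, no costs and no adverse events.
null_strategy <- function(key = "null", dur = 0L) {
  strategy_spec(
    key = key, name = key, adjuvant_duration = dur, adjuvant_cost_zar = 0,
    first_line = list(regimen = "NONE", cost_zar = 0, duration = 6L),
    second_line = list(regimen = "NONE", cost_zar = 0, duration = 6L),
    pr_stratum = "doublet"
  )
}

# Build a minimal cohort_trace from an explicit occupancy matrix (rows are
# cycle boundaries 0..h, columns the six model states) so economics
# operations can be checked against hand arithmetic.
fake_trace <- function(occupancy, flows = NULL, r = 0.05, start_age = 60) {
  h <- nrow(occupancy) - 1L
  states <- c("DISEASE_FREE", "REC_HEPATECTOMY", "REC_FIRST_LINE",
              "REC_SECOND_LINE", "DEAD_CC", "DEAD_OTHER")
  colnames(occupancy) <- states
  if (is.null(flows)) {
    flows <- tibble::tibble(
      new_recurrence = numeric(h), new_hepatectomy = numeric(h),
      new_first_line = numeric(h), new_second_line = numeric(h),
      new_dead_cc = numeric(h), new_dead_other = numeric(h),
      entry_boundary = seq_len(h)
    )
  }
  settings <- model_settings(start_age = start_age, annual_discount_rate = r,
                             horizon = h)
  structure(
    list(occupancy = occupancy,
         half_cycle = (occupancy[-1L, , drop = FALSE] +
                         occupancy[-(h + 1L), , drop = FALSE]) / 2,
         flows = flows, on_treatment_hc = numeric(h),
         bg_survival = rep(1, h + 1L), settings = settings,
         pathway = recurrence_pathway(), strategy_name = "fake",
         first_line_duration = 6L, second_line_duration = 6L),
    class = "cohort_trace"
  )
}

# Empty shared-cost table (all rows present, all zero).
zero_costs <- function() {
  shared <- c(hepatectomy = 0, bloodwork = 0, ct_scan = 0, colonoscopy = 0,
              neuropathy = 0, neuropathy_annual = 0, diarrhea = 0,
              febrile_neutropenia = 0, nausea_vomiting = 0, mucositis = 0,
              hand_foot = 0, transportation_day = 0, lost_wages_day = 0)
  list(shared = shared,
       surveillance = data.frame(month = integer(0), item = character(0),
                                 person_days = numeric(0)))
}
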