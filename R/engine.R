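# Cohort engine: discrete-time Markov simulation of one adjuvant strategy.
#
# States: DISEASE_FREE; RECURRENCE split at entry into a curative-intent
# hepatectomy pathway and a chemotherapy pathway (first line, then second
# line, then best supportive care), each represented as a tunnel indexed by
# months since recurrence so post-recurrence mortality can be time-indexed;
# and two absorbing death states (colon cancer death, death from all other
# causes). Cycle length is one month; a trapezoidal half-cycle correction is
# applied to state time.

#' Model settings
#'
#' @param start_age Cohort age in years at model entry (base case 60;
#'   accepted range 40 to 80).
#' @param max_age Age at which simulation stops (base case 85).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   disability (base case 0.05; accepted range 0 to 0.10).
#' @param horizon Number of monthly cycles; defaults to
#'   `min(300, 12 * (max_age - start_age))`.
#'
#' @return A `model_settings` list.
#' @export
model_settings <- function(start_age = 60, max_age = 85,
                           annual_discount_rate = 0.05, horizon = NULL) {
  if (start_age < 40 || start_age > 80) stop("`start_age` must lie in [40, 80]")
  if (annual_discount_rate < 0 || annual_discount_rate > 0.10) {
    stop("`annual_discount_rate` must lie in [0, 0.10]")
  }
  if (is.null(horizon)) horizon <- min(300L, as.integer(12 * (max_age - start_age)))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be at least one cycle")
  structure(
    list(start_age = start_age, max_age = max_age, cycle_length = 1L,
         annual_discount_rate = annual_discount_rate, horizon = horizon),
    class = "model_settings"
  )
}

#' Recurrence pathway split
#'
#' At recurrence entry the cohort is split once: a fraction
#' `frac_liver_only * frac_hepatectomy_given_liver_only` (base case
#' 1/3 x 1/3 = 1/9) undergoes curative-intent hepatectomy; everyone else
#' enters first-line palliative chemotherapy, with at most
#' `max_treatment_lines` lines per patient.
#'
#' @param frac_liver_only Fraction of recurrences that are liver-only.
#' @param frac_hepatectomy_given_liver_only Fraction of liver-only
#'   recurrences resected with curative intent.
#' @param max_treatment_lines Maximum chemotherapy lines (fixed at 2).
#'
#' @return A `recurrence_pathway` list.
#' @export
recurrence_pathway <- function(frac_liver_only = 1 / 3,
                               frac_hepatectomy_given_liver_only = 1 / 3,
                               max_treatment_lines = 2L) {
  if (frac_liver_only < 0 || frac_liver_only > 1 ||
      frac_hepatectomy_given_liver_only < 0 || frac_hepatectomy_given_liver_only > 1) {
    stop("pathway fractions must lie in [0, 1]")
  }
  if (max_treatment_lines != 2L) stop("the model allows exactly two treatment lines")
  structure(
    list(frac_liver_only = frac_liver_only,
         frac_hepatectomy_given_liver_only = frac_hepatectomy_given_liver_only,
         max_treatment_lines = 2L),
    class = "recurrence_pathway"
  )
}

#' Transition schedule set
#'
#' Bundles the three monthly probability schedules one strategy needs:
#' recurrence indexed by cycle since model start, post-recurrence colon
#' cancer death indexed by months since recurrence (one stratum already
#' chosen for the strategy's adjuvant arm), and background mortality indexed
#' by cycle (derived from attained age). All probabilities are validated at
#' load, not mid-run.
#'
#' @param p_recur Monthly recurrence probabilities. Beyond its support
#'   recurrence risk is treated as exhausted (probability 0).
#' @param p_death_cc Monthly colon cancer death probabilities by months
#'   since recurrence.
#' @param p_death_other Monthly background mortality by cycle.
#'
#' @return A `transition_schedules` list.
#' @export
transition_schedules <- function(p_recur, p_death_cc, p_death_other) {
  for (nm in c("p_recur", "p_death_cc", "p_death_other")) {
    p <- get(nm)
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
      stop(sprintf("%s: probabilities must be numeric in [0, 1]", nm))
    }
  }
  structure(
    list(p_recur = as.numeric(p_recur), p_death_cc = as.numeric(p_death_cc),
         p_death_other = as.numeric(p_death_other)),
    class = "transition_schedules"
  )
}

.state_names <- c("DISEASE_FREE", "REC_HEPATECTOMY", "REC_FIRST_LINE",
                  "REC_SECOND_LINE", "DEAD_CC", "DEAD_OTHER")

#' Run the Markov cohort simulation for one strategy
#'
#' Competing risks within a cycle are resolved death-other first: from the
#' disease-free state, `P(recurrence this cycle) = (1 - p_death_other) *
#' p_recur`; from recurrence, background death is applied before colon
#' cancer death. Colon cancer death is only reachable from recurrence.
#' New recurrences enter the tunnel at months-since-recurrence 0 and are
#' split across pathways by the [recurrence_pathway()] fractions;
#' chemotherapy-pathway patients move from first to second line after the
#' strategy's first-line duration.
#'
#' @param settings A [model_settings()].
#' @param strategy A [strategy_spec()] (only the treatment-line durations
#'   are used by the engine).
#' @param schedules A [transition_schedules()]. `p_death_cc` and
#'   `p_death_other` must cover the horizon; `p_recur` is zero-padded.
#' @param pathway A [recurrence_pathway()].
#'
#' @return A `cohort_trace`: list with `occupancy` (state fractions at each
#'   cycle boundary, rows summing to 1), `half_cycle` (trapezoidal state
#'   time per cycle), `flows` (per-cycle fractions newly entering
#'   recurrence, hepatectomy, treatment lines and death states, with the
#'   0-based entry boundary), `on_treatment_hc` (half-cycle occupancy of
#'   active chemotherapy lines), and `bg_survival` (cumulative survival
#'   under background mortality alone).
#' @export
run_cohort <- function(settings, strategy, schedules,
                       pathway = recurrence_pathway()) {
  stopifnot(inherits(settings, "model_settings"),
            inherits(schedules, "transition_schedules"))
  h <- settings$horizon
  pr <- schedules$p_recur
  if (length(pr) < h) pr <- c(pr, numeric(h - length(pr)))
  pr <- pr[seq_len(h)]
  pdc <- schedules$p_death_cc
  if (length(pdc) < h) {
    stop(sprintf("p_death_cc schedule covers %d cycles but the horizon is %d (deficit %d)",
                 length(pdc), h, h - length(pdc)))
  }
  pdc <- pdc[seq_len(h)]
  pdo <- schedules$p_death_other
  if (length(pdo) < h) {
    stop(sprintf("p_death_other schedule covers %d cycles but the horizon is %d (deficit %d)",
                 length(pdo), h, h - length(pdo)))
  }
  pdo <- pdo[seq_len(h)]

  f_hep <- pathway$frac_liver_only * pathway$frac_hepatectomy_given_liver_only
  d1 <- strategy$first_line$duration
  d2 <- strategy$second_line$duration
  stopifnot(d1 >= 1L, d2 >= 0L)
  on_max <- min(d1 + d2, h)
  first_idx <- seq_len(min(d1, h))
  second_idx <- if (d1 < h) (d1 + 1L):h else integer(0)

  occ <- matrix(0, h + 1L, 6L, dimnames = list(NULL, .state_names))
  occ[1L, 1L] <- 1
  flow_names <- c("new_recurrence", "new_hepatectomy", "new_first_line",
                  "new_second_line", "new_dead_cc", "new_dead_other")
  fl <- matrix(0, h, 6L, dimnames = list(NULL, flow_names))
  on_trt <- numeric(h + 1L)
  bg <- numeric(h + 1L)
  bg[1L] <- 1

  df <- 1
  hep <- numeric(h)   # tunnel: index i holds months_since_recurrence i - 1
  chem <- numeric(h)
  dcc <- 0
  doth <- 0

  for (t in seq_len(h)) {
    q <- pdo[t]
    df_die <- df * q
    surv <- df - df_die
    new_rec <- surv * pr[t]
    df <- surv - new_rec

    hep_o <- hep * q
    hep_s <- hep - hep_o
    hep_c <- hep_s * pdc
    hep_s <- hep_s - hep_c
    ch_o <- chem * q
    ch_s <- chem - ch_o
    ch_c <- ch_s * pdc
    ch_s <- ch_s - ch_c

    # advance the tunnels one month; new recurrences enter at month 0
    hep <- c(new_rec * f_hep, hep_s[-h])
    chem <- c(new_rec * (1 - f_hep), ch_s[-h])
    new_second <- if (d1 < h) chem[d1 + 1L] else 0

    cyc_dcc <- sum(hep_c) + sum(ch_c)
    cyc_do <- df_die + sum(hep_o) + sum(ch_o)
    dcc <- dcc + cyc_dcc
    doth <- doth + cyc_do
    bg[t + 1L] <- bg[t] * (1 - q)

    occ[t + 1L, ] <- c(df, sum(hep), sum(chem[first_idx]),
                       sum(chem[second_idx]), dcc, doth)
    on_trt[t + 1L] <- sum(chem[seq_len(on_max)])
    fl[t, ] <- c(new_rec, new_rec * f_hep, new_rec * (1 - f_hep),
                 new_second, cyc_dcc, cyc_do)
  }

  hc <- (occ[-1L, , drop = FALSE] + occ[-(h + 1L), , drop = FALSE]) / 2
  flows <- tibble::as_tibble(fl)
  flows$entry_boundary <- seq_len(h) # 0-based month at which the entry state is reached

  structure(
    list(occupancy = occ, half_cycle = hc, flows = flows,
         on_treatment_hc = (on_trt[-1L] + on_trt[-(h + 1L)]) / 2,
         bg_survival = bg, settings = settings, pathway = pathway,
         strategy_name = strategy$name,
         first_line_duration = d1, second_line_duration = d2),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  h <- x$settings$horizon
  cat(sprintf("<cohort_trace> '%s': %d cycles, OS %.2f years, final DEAD_CC %.3f, DEAD_OTHER %.3f\n",
              x$strategy_name %||% "?", h, overall_survival_years(x),
              x$occupancy[h + 1L, "DEAD_CC"], x$occupancy[h + 1L, "DEAD_OTHER"]))
  invisible(x)
}

#' Undiscounted overall survival in life years
#'
#' Half-cycle-corrected time in the alive states (disease-free plus all
#' recurrence substates), divided by 12. Undiscounted and unadjusted for
#' disability.
#'
#' @param trace A [run_cohort()] trace.
#' @return Overall survival in years.
#' @export
overall_survival_years <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(trace$half_cycle[, 1:4]) / 12
}

#' Model disease-free survival at a given month
#'
#' The disease-free occupancy is divided by a background-mortality
#' denominator so model DFS is comparable with trial DFS curves that carry
#' no South African background mortality. The default denominator is the
#' cumulative survival under background mortality alone, which makes the
#' calibration round trip exact; `"dead_other_complement"` uses
#' `1 - DEAD_OTHER` instead.
#'
#' @param trace A [run_cohort()] trace.
#' @param month Month (cycle boundary) at which to evaluate, default 60.
#' @param denominator Background-mortality adjustment; see Details.
#' @return Disease-free survival fraction.
#' @export
dfs_at <- function(trace, month = 60,
                   denominator = c("background_survival", "dead_other_complement")) {
  stopifnot(inherits(trace, "cohort_trace"))
  denominator <- match.arg(denominator)
  if (month > trace$settings$horizon) {
    stop(sprintf("month %d exceeds the %d-cycle horizon", month, trace$settings$horizon))
  }
  i <- month + 1L
  den <- switch(denominator,
                background_survival = trace$bg_survival[i],
                dead_other_complement = 1 - trace$occupancy[i, "DEAD_OTHER"])
  trace$occupancy[i, "DISEASE_FREE"] / den
}

#' Internal validation: model DFS against the calibration curve
#'
#' Compares the engine's background-mortality-adjusted disease-free survival
#' at 60 months against the 5-year survival of the curve the recurrence
#' schedule was derived from, returning the relative error. The model is
#' considered internally valid when this error is below 1.5 percent for
#' every strategy and stage.
#'
#' @param trace A [run_cohort()] trace built from schedules derived from
#'   `calibration_curve`.
#' @param calibration_curve The source [survival_curve()]; must cover 60
#'   months (no extrapolation).
#' @param month Validation month, default 60.
#' @inheritParams dfs_at
#' @return Relative error `|model - curve| / curve` at `month`.
#' @export
validate_dfs <- function(trace, calibration_curve, month = 60,
                         denominator = c("background_survival", "dead_other_complement")) {
  stopifnot(inherits(calibration_curve, "survival_curve"))
  if (max(calibration_curve$time) < month) {
    stop(sprintf("calibration curve ends at %g months; cannot validate at %d",
                 max(calibration_curve$time), month))
  }
  s_curve <- resample_monthly(calibration_curve, months = month)[month + 1L]
  if (s_curve <= 0) stop("calibration curve survival is 0 at the validation month")
  s_model <- dfs_at(trace, month = month, denominator = match.arg(denominator))
  abs(s_model - s_curve) / s_curve
}
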