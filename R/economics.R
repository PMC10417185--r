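# Economics: discounted societal costs, DALY accounting (YLL + YLD), net
# monetary benefit, and the cost-effectiveness frontier with extended
# dominance.

#' Economic settings
#'
#' @param wtp Willingness-to-pay threshold in international dollars per DALY
#'   averted (base case 13,764, the 2021 South African GDP per capita).
#' @param ppp_factor ZAR per international dollar at 2021 purchasing power
#'   parity (7.097).
#' @param annual_discount_rate Annual discount rate (shared with
#'   [model_settings()]).
#' @param comparator Strategy key used as the DALYs-averted comparator.
#'
#' @return An `econ_settings` list.
#' @export
econ_settings <- function(wtp = 13764, ppp_factor = 7.097,
                          annual_discount_rate = 0.05,
                          comparator = "no_adjuvant") {
  if (wtp <= 0 || ppp_factor <= 0) stop("`wtp` and `ppp_factor` must be positive")
  structure(
    list(wtp = wtp, ppp_factor = ppp_factor,
         annual_discount_rate = annual_discount_rate, comparator = comparator),
    class = "econ_settings"
  )
}

#' Convert 2021 South African rand to international dollars
#'
#' Division by the 2021 purchasing power parity factor (7.097 ZAR per I$).
#' Values are kept unrounded internally; [int_display()] rounds half-up to
#' the nearest dollar for display.
#'
#' @param zar Non-negative amount(s) in 2021 ZAR.
#' @param ppp_factor ZAR per I$.
#' @return Amount(s) in I$, unrounded.
#' @export
#' @examples
#' int_display(convert_currency(9748))  # 1374
#' int_display(convert_currency(13266)) # 1869
convert_currency <- function(zar, ppp_factor = 7.097) {
  if (any(zar < 0)) stop("ZAR amounts must be non-negative")
  zar / ppp_factor
}

#' @rdname convert_currency
#' @param x Numeric value(s) to round half-up to the nearest integer.
#' @export
int_display <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Annual disability weights
#'
#' Base-case annual disability weights: 0 while disease-free, 0.451 during
#' metastatic recurrence, 1 for colon cancer death (years in the colon
#' cancer death state accrue as years of life lost within the horizon), and
#' event weights for grade 3/4 treatment-related adverse events. All-cause
#' death accrues nothing.
#'
#' @param recurrence,cc_death State weights.
#' @param ae Named vector of adverse-event weights.
#' @return A `disability_weights` list.
#' @export
disability_weights <- function(recurrence = 0.451, cc_death = 1,
                               ae = c(neuropathy = 0.133, diarrhea = 0.247,
                                      febrile_neutropenia = 0.133,
                                      nausea_vomiting = 0.114,
                                      mucositis = 0.051, hand_foot = 0.133)) {
  w <- c(recurrence, cc_death, ae)
  if (any(w < 0 | w > 1)) stop("disability weights must lie in [0, 1]")
  structure(list(recurrence = recurrence, cc_death = cc_death, ae = ae),
            class = "disability_weights")
}

# Monthly discount factors under annual-equivalent compounding:
# a cash flow at month m is discounted by (1 + r)^(-m / 12), so a cost 12
# cycles out is worth exactly 1 / (1 + r) of its face value.
.disc_boundary <- function(r, h) (1 + r)^(-(0:h) / 12)
.disc_mid <- function(r, h) (1 + r)^(-(seq_len(h) - 0.5) / 12)

#' Discounted lifetime societal cost of a strategy
#'
#' One-time costs attach to event flows at their entry boundary (no
#' half-cycle correction): metastatic line courses at line entry,
#' hepatectomy at recurrence entry, surveillance items on the visit
#' calendar, and acute adverse-event costs at model start. Per-state-time
#' costs (adjuvant course spread uniformly over the treatment months,
#' residual neuropathy annuity for 36 months post-treatment, indirect
#' per-visit-day costs) accrue on half-cycle-corrected state time and are
#' discounted at mid-cycle. Indirect costs follow the visit convention: CT
#' per patient; colonoscopy and treatment months per patient plus one
#' caregiver.
#'
#' @param trace A [run_cohort()] trace for the strategy.
#' @param strategy The [strategy_spec()] the trace was run with.
#' @param costs Shared cost inputs: list with `shared` (named ZAR vector
#'   covering hepatectomy, surveillance items, adverse events,
#'   neuropathy_annual, transportation_day, lost_wages_day) and
#'   `surveillance` (data frame `month, item, person_days`).
#' @param econ An [econ_settings()]; its discount rate is used.
#'
#' @return List with `total_zar`, `total_int` and a `breakdown` tibble.
#' @export
discounted_costs <- function(trace, strategy, costs, econ) {
  stopifnot(inherits(trace, "cohort_trace"))
  h <- trace$settings$horizon
  r <- econ$annual_discount_rate
  vb <- .disc_boundary(r, h)
  vm <- .disc_mid(r, h)
  hc <- trace$half_cycle
  fl <- trace$flows
  shared <- costs$shared
  need <- c("hepatectomy", "bloodwork", "ct_scan", "colonoscopy",
            "neuropathy_annual", "transportation_day", "lost_wages_day",
            names(strategy$ae_incidence))
  missing_rows <- setdiff(need, names(shared))
  if (length(missing_rows)) {
    stop("missing cost rows: ", paste(missing_rows, collapse = ", "))
  }
  day_cost <- shared[["transportation_day"]] + shared[["lost_wages_day"]]
  alive_hc <- rowSums(hc[, 1:4, drop = FALSE])

  dur <- strategy$adjuvant_duration
  adj <- 0
  ind_adj <- 0
  ae_acute <- 0
  resid <- 0
  if (dur > 0) {
    m <- seq_len(min(dur, h))
    df_time <- hc[m, "DISEASE_FREE"]
    adj <- sum(strategy$adjuvant_cost_zar / dur * df_time * vm[m])
    # one treatment visit-day per month, patient plus caregiver
    ind_adj <- sum(2 * day_cost * df_time * vm[m])
    ae_acute <- sum(strategy$ae_incidence * shared[names(strategy$ae_incidence)])
    rn <- (min(dur, h) + 1L):min(dur + 36L, h)
    if (length(rn) && rn[1L] <= h) {
      resid <- strategy$residual_neuropathy_incidence *
        shared[["neuropathy_annual"]] / 12 * sum(alive_hc[rn] * vm[rn])
    }
  }

  vb_entry <- vb[fl$entry_boundary + 1L]
  hep_cost <- shared[["hepatectomy"]] * sum(fl$new_hepatectomy * vb_entry)
  line1 <- strategy$first_line$cost_zar * sum(fl$new_first_line * vb_entry)
  line2 <- strategy$second_line$cost_zar * sum(fl$new_second_line * vb_entry)
  # metastatic treatment visit-days: patient plus caregiver while on a line
  ind_line <- sum(2 * day_cost * trace$on_treatment_hc * vm)

  surv_cost <- 0
  ind_surv <- 0
  cal <- costs$surveillance
  if (!is.null(cal) && nrow(cal)) {
    keep <- cal$month <= h
    cal <- cal[keep, , drop = FALSE]
    df_at <- trace$occupancy[cal$month + 1L, "DISEASE_FREE"]
    v_at <- vb[cal$month + 1L]
    surv_cost <- sum(shared[cal$item] * df_at * v_at)
    ind_surv <- sum(cal$person_days * day_cost * df_at * v_at)
  }

  breakdown <- tibble::tibble(
    component = c("adjuvant_course", "adverse_events_acute",
                  "residual_neuropathy", "hepatectomy", "first_line",
                  "second_line", "surveillance", "indirect"),
    zar = c(adj, ae_acute, resid, hep_cost, line1, line2, surv_cost,
            ind_adj + ind_line + ind_surv)
  )
  total_zar <- sum(breakdown$zar)
  list(total_zar = total_zar,
       total_int = convert_currency(total_zar, econ$ppp_factor),
       breakdown = breakdown)
}

#' Disability-adjusted life years for a strategy
#'
#' `DALY = YLL + YLD`, discounted, without age weighting. YLL is the
#' half-cycle-corrected time spent in the colon cancer death state within
#' the horizon, weighted 1 (all-cause death accrues nothing). YLD is
#' recurrence state time weighted 0.451 per year, plus acute adverse-event
#' disability during the treatment months and the residual neuropathy
#' annuity over the 36 months post-treatment.
#'
#' @inheritParams discounted_costs
#' @param weights A [disability_weights()].
#' @return A tibble with `yll`, `yld` and `daly` (years).
#' @export
compute_dalys <- function(trace, strategy, weights, econ) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(weights, "disability_weights"))
  h <- trace$settings$horizon
  vm <- .disc_mid(econ$annual_discount_rate, h)
  hc <- trace$half_cycle

  yll <- weights$cc_death / 12 * sum(hc[, "DEAD_CC"] * vm)
  rec_time <- rowSums(hc[, 2:4, drop = FALSE])
  yld <- weights$recurrence / 12 * sum(rec_time * vm)

  dur <- strategy$adjuvant_duration
  if (dur > 0) {
    m <- seq_len(min(dur, h))
    ae_w <- weights$ae[names(strategy$ae_incidence)]
    # each acute grade 3/4 event carries one month of its weight
    yld <- yld + sum(strategy$ae_incidence * ae_w) / 12 * mean(vm[m])
    rn <- (min(dur, h) + 1L):min(dur + 36L, h)
    if (length(rn) && rn[1L] <= h) {
      alive_hc <- rowSums(hc[, 1:4, drop = FALSE])
      yld <- yld + strategy$residual_neuropathy_incidence *
        weights$ae[["neuropathy"]] / 12 * sum(alive_hc[rn] * vm[rn])
    }
  }
  tibble::tibble(yll = yll, yld = yld, daly = yll + yld)
}

#' Net monetary benefit
#'
#' `NMB = WTP x DALYs averted - cost`, at full precision.
#'
#' @param cost Discounted cost (I$).
#' @param dalys_averted Discounted DALYs averted versus the comparator.
#' @param wtp Willingness-to-pay per DALY averted (I$).
#' @return NMB in I$.
#' @export
net_monetary_benefit <- function(cost, dalys_averted, wtp) {
  wtp * dalys_averted - cost
}

#' Cost-effectiveness frontier with dominance classification
#'
#' Strategies are sorted by ascending cost (ties broken by higher
#' effectiveness). A strategy is strictly dominated when some other strategy
#' is no costlier and no less effective (and differs in at least one).
#' Sequential ICERs are computed between each remaining strategy and the
#' next-less-costly remaining strategy; a strategy whose sequential ICER
#' exceeds that of the next-costlier remaining strategy is extended
#' dominated. By default the reported ICERs are *not* recomputed after
#' extended-dominance removal (the reporting convention of the source
#' analysis); set `recompute_extended = TRUE` for the textbook convention.
#' The recommended strategy is the costliest frontier member whose ICER does
#' not exceed `wtp`.
#'
#' @param results Data frame with columns `strategy`, `cost` (I$) and
#'   `dalys_averted` (vs the common comparator). Extra columns pass through.
#' @param wtp Willingness-to-pay threshold (I$ per DALY averted).
#' @param recompute_extended Recompute sequential ICERs after removing
#'   extended-dominated strategies (default `FALSE`).
#'
#' @return A `cea_frontier` tibble: the input plus `icer`, `nmb`,
#'   `dominance` (`REFERENCE`, `UNDOMINATED`, `DOMINATED`,
#'   `EXTENDED_DOMINATED`) and logical `recommended`.
#' @export
#' @examples
#' frontier(data.frame(
#'   strategy = c("none", "cape6", "capox3", "capox6"),
#'   cost = c(2693, 3748, 4083, 5398),
#'   dalys_averted = c(0, 0.87, 2.21, 2.28)
#' ), wtp = 13764)
frontier <- function(results, wtp, recompute_extended = FALSE) {
  res <- tibble::as_tibble(results)
  need <- c("strategy", "cost", "dalys_averted")
  if (!all(need %in% names(res))) {
    stop("`results` needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(res) < 1L) stop("at least one strategy is required")
  if (anyDuplicated(res$cost)) {
    message("tied costs: breaking ties by higher effectiveness")
  }
  res <- res[order(res$cost, -res$dalys_averted), ]
  n <- nrow(res)
  cost <- res$cost
  eff <- res$dalys_averted

  # after the cost/effect sort, a strategy is (weakly) dominated iff some
  # earlier strategy is at least as effective; exact duplicates keep their
  # first occurrence on the frontier
  dominated <- c(FALSE, eff[-1L] <= cummax(eff)[-n])

  icer <- rep(NA_real_, n)
  label <- ifelse(dominated, "DOMINATED", NA_character_)
  chain <- which(!dominated)
  label[chain[1L]] <- "REFERENCE"
  seq_icer <- function(chain) {
    ic <- rep(NA_real_, n)
    if (length(chain) > 1L) {
      for (k in 2:length(chain)) {
        i <- chain[k]
        j <- chain[k - 1L]
        ic[i] <- (cost[i] - cost[j]) / (eff[i] - eff[j])
      }
    }
    ic
  }
  icer <- seq_icer(chain)
  ext <- logical(n)
  if (!recompute_extended) {
    if (length(chain) > 2L) {
      for (k in 2:(length(chain) - 1L)) {
        if (icer[chain[k]] > icer[chain[k + 1L]]) ext[chain[k]] <- TRUE
      }
    }
  } else {
    repeat {
      keep <- setdiff(chain, which(ext))
      icer <- seq_icer(keep)
      if (length(keep) <= 2L) break
      ks <- 2:(length(keep) - 1L)
      bad <- ks[icer[keep[ks]] > icer[keep[ks + 1L]]]
      if (!length(bad)) break
      ext[keep[bad[1L]]] <- TRUE
    }
  }
  label[ext] <- "EXTENDED_DOMINATED"
  icer[ext | dominated] <- NA_real_
  label[is.na(label)] <- "UNDOMINATED"

  res$icer <- icer
  res$nmb <- net_monetary_benefit(cost, eff, wtp)
  res$dominance <- label
  members <- which(label %in% c("REFERENCE", "UNDOMINATED"))
  ok <- members[is.na(icer[members]) | icer[members] <= wtp]
  res$recommended <- seq_len(n) == max(ok)
  attr(res, "wtp") <- wtp
  class(res) <- c("cea_frontier", class(res))
  res
}

#' @export
print.cea_frontier <- function(x, ...) {
  y <- tibble::as_tibble(x)
  y$cost <- int_display(y$cost)
  y$dalys_averted <- round(y$dalys_averted, 2)
  y$icer <- int_display(y$icer)
  y$nmb <- int_display(y$nmb)
  cat(sprintf("Cost-effectiveness frontier (WTP = %s I$/DALY averted)\n",
              format(attr(x, "wtp"), big.mark = ",")))
  print(y, ...)
  invisible(x)
}

#' Published South African base-case results used as frontier inputs
#'
#' Reference discounted lifetime cost (I$), undiscounted overall survival
#' (years) and DALYs averted per strategy for the South African public
#' sector base case, as printed in the source analysis. These pairs serve
#' as direct inputs to [frontier()] so the frontier, dominance and NMB
#' logic can be exercised independently of curve calibration.
#'
#' @return A tibble with columns `stage`, `strategy`, `label`, `cost_int`,
#'   `cost_zar`, `os_years` and `dalys_averted`.
#' @export
reference_base_case <- function() {
  tibble::tibble(
    stage = rep(c("HIGH_RISK_II", "III"), each = 4L),
    strategy = rep(c("no_adjuvant", "cape6", "capox3", "capox6"), 2L),
    label = rep(c("No adjuvant chemotherapy", "Capecitabine 6 months",
                  "CAPOX 3 months", "CAPOX 6 months"), 2L),
    cost_int = c(2693, 3748, 4083, 5398, 5117, 3737, 5279, 6647),
    cost_zar = c(19111, 26598, 28974, 38312, 36316, 26522, 37463, 47172),
    os_years = c(13.69, 14.34, 15.33, 15.39, 9.00, 11.87, 12.99, 12.79),
    dalys_averted = c(0, 0.87, 2.21, 2.28, 0, 3.98, 5.46, 5.19)
  )
}
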