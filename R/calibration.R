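# Calibration: survival curves, hazard ratios and life tables are turned into
# the monthly transition probability schedules the cohort engine consumes.

#' Survival curve
#'
#' A survival curve is an ordered set of `(time, survival)` points on a
#' monthly time axis. Survival must start at 1, be non-increasing, and times
#' must be strictly increasing. A point at time 0 is prepended when absent.
#'
#' @param time Numeric vector of times in months, strictly increasing.
#' @param survival Numeric vector of survival fractions in `[0, 1]`,
#'   non-increasing, with `survival = 1` at `time = 0`.
#' @param label Stratum label, e.g. which adjuvant arm the curve describes.
#'
#' @return An object of class `survival_curve`: a list with elements `time`,
#'   `survival` and `label`.
#' @export
#' @examples
#' sc <- survival_curve(0:60, exp(-0.01 * (0:60)))
#' head(curve_to_monthly_probs(sc))
survival_curve <- function(time, survival, label = "curve") {
  if (!is.numeric(time) || !is.numeric(survival) ||
      length(time) != length(survival) || length(time) < 2L) {
    stop("`time` and `survival` must be numeric vectors of equal length >= 2")
  }
  if (any(diff(time) <= 0)) stop("curve times must be strictly increasing")
  if (time[1L] > 0) {
    time <- c(0, time)
    survival <- c(1, survival)
  }
  if (abs(survival[1L] - 1) > 1e-9) stop("survival at time 0 must be 1")
  if (any(survival < -1e-12 | survival > 1 + 1e-12)) {
    stop("survival values must lie in [0, 1]")
  }
  if (any(diff(survival) > 1e-12)) stop("survival must be non-increasing")
  structure(
    list(time = as.numeric(time),
         survival = pmin(pmax(as.numeric(survival), 0), 1),
         label = label),
    class = "survival_curve"
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> '%s': %d points over %g months, S(end) = %.4f\n",
              x$label, length(x$time), max(x$time),
              x$survival[length(x$survival)]))
  invisible(x)
}

#' Resample a survival curve onto the monthly grid
#'
#' Interpolation is linear on log-survival, which is exact for exponential
#' (constant-hazard) segments. Zero-survival tails are kept at zero. No
#' extrapolation beyond the last observed time is performed.
#'
#' @param curve A [survival_curve()].
#' @param months Last month of the grid; defaults to the floor of the last
#'   observed curve time.
#'
#' @return Numeric vector of survival values at months `0:months`.
#' @export
resample_monthly <- function(curve, months = NULL) {
  stopifnot(inherits(curve, "survival_curve"))
  tmax <- max(curve$time)
  if (is.null(months)) months <- floor(tmax)
  if (months > tmax + 1e-9) {
    stop(sprintf("curve support ends at %g months; cannot resample to %d (no extrapolation)",
                 tmax, months))
  }
  grid <- 0:months
  logs <- log(curve$survival) # -Inf where survival is exactly 0
  s <- exp(stats::approx(curve$time, logs, xout = grid, method = "linear",
                         rule = 1, ties = "ordered")$y)
  s[is.na(s) | is.nan(s)] <- 0
  s
}

#' Convert a survival curve into monthly transition probabilities
#'
#' The curve is resampled onto the monthly grid and converted through the
#' discrete-hazard identity `p[t] = 1 - S(t + 1) / S(t)`. When survival
#' reaches 0 the sequence terminates with probability 1 at that month.
#'
#' @param curve A [survival_curve()].
#' @param horizon Optional number of months to convert; defaults to the full
#'   curve support.
#'
#' @return Numeric vector of monthly probabilities, element `t` covering the
#'   half-open cycle `[t - 1, t)` months.
#' @export
curve_to_monthly_probs <- function(curve, horizon = NULL) {
  s <- resample_monthly(curve, months = horizon)
  n <- length(s) - 1L
  prev <- s[seq_len(n)]
  p <- 1 - s[-1L] / prev
  if (any(prev == 0)) {
    z <- which(prev == 0)[1L] # first month entered with S = 0
    p <- p[seq_len(z - 1L)]   # p[z - 1] = 1 - 0/S = 1 terminates the sequence
  }
  pmin(pmax(p, 0), 1)
}

#' Apply a hazard ratio to a sequence of monthly probabilities
#'
#' Uses the proportional-hazards transform on the discrete survival ratio,
#' `p' = 1 - (1 - p)^HR`, so that cumulative survival is raised to the power
#' `HR`. Composition of two adjustments equals a single adjustment by the
#' product of the hazard ratios.
#'
#' @param probs Numeric vector of monthly probabilities in `[0, 1]`.
#' @param hazard_ratio Positive hazard ratio (base case 1.61 for survival
#'   after recurrence in the single-agent / no-adjuvant stratum).
#'
#' @return Adjusted monthly probability vector.
#' @export
#' @examples
#' apply_hazard_ratio(0.1, 2) # 1 - 0.9^2 = 0.19
apply_hazard_ratio <- function(probs, hazard_ratio) {
  if (!is.numeric(hazard_ratio) || length(hazard_ratio) != 1L ||
      !is.finite(hazard_ratio) || hazard_ratio <= 0) {
    stop("`hazard_ratio` must be a single positive number")
  }
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (hazard_ratio == 1) return(probs)
  1 - (1 - probs)^hazard_ratio
}

#' Abridged life table
#'
#' WHO-style abridged life table: contiguous, non-overlapping age bands with
#' an annual probability of death per band.
#'
#' @param age_lower,age_upper Band bounds in years; bands must be contiguous
#'   (`age_upper[i] == age_lower[i + 1]`).
#' @param annual_death_prob Annual death probability per band, in `[0, 1]`.
#'
#' @return A `life_table` data frame.
#' @export
life_table <- function(age_lower, age_upper, annual_death_prob) {
  stopifnot(length(age_lower) == length(age_upper),
            length(age_lower) == length(annual_death_prob))
  if (any(age_upper <= age_lower)) stop("each band must have age_upper > age_lower")
  if (length(age_lower) > 1L &&
      any(abs(age_lower[-1L] - age_upper[-length(age_upper)]) > 1e-9)) {
    stop("life table bands must be contiguous and non-overlapping")
  }
  if (any(annual_death_prob < 0 | annual_death_prob > 1)) {
    stop("annual death probabilities must lie in [0, 1]")
  }
  structure(
    data.frame(age_lower = age_lower, age_upper = age_upper,
               annual_death_prob = annual_death_prob),
    class = c("life_table", "data.frame")
  )
}

#' Convert a life table into a cycle-indexed monthly mortality schedule
#'
#' For each model cycle the attained (fractional) age is looked up in the
#' band containing it and the band's annual probability is converted to a
#' monthly probability via `1 - (1 - q)^(1/12)`, so that twelve consecutive
#' cycles inside one band compound back to the annual probability.
#'
#' @param table A [life_table()].
#' @param start_age Age in years at model entry.
#' @param horizon Number of monthly cycles to cover.
#'
#' @return Numeric vector of monthly death probabilities, one per cycle.
#' @export
life_table_to_monthly <- function(table, start_age, horizon) {
  stopifnot(inherits(table, "life_table"), horizon >= 1)
  age <- start_age + (seq_len(horizon) - 1L) / 12
  idx <- findInterval(age, table$age_lower)
  bad <- idx < 1L | age >= table$age_upper[pmax(idx, 1L)]
  if (any(bad)) {
    stop(sprintf("life table does not cover attained age %.2f (cycle %d)",
                 age[which(bad)[1L]], which(bad)[1L] - 1L))
  }
  1 - (1 - table$annual_death_prob[idx])^(1 / 12)
}

# ---- CSV interfaces --------------------------------------------------------

#' Read and write calibration inputs as CSV
#'
#' Survival curves use columns `time_months, survival`; life tables use
#' `age_lower, age_upper, annual_death_probability`; transition schedules use
#' `cycle_index, probability` with 0-based cycles over half-open month
#' intervals. Loaders validate on read so malformed inputs fail at load time,
#' not mid-simulation.
#'
#' @param path File path.
#' @param curve,table,probs Object to write.
#' @param label Stratum label attached to a curve on read.
#' @name calibration_io
NULL

#' @rdname calibration_io
#' @export
read_survival_curve <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(d))) {
    stop(sprintf("%s: expected columns time_months, survival", path))
  }
  survival_curve(d$time_months, d$survival, label = label)
}

#' @rdname calibration_io
#' @export
write_survival_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(time_months = curve$time, survival = curve$survival),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  need <- c("age_lower", "age_upper", "annual_death_probability")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  life_table(d$age_lower, d$age_upper, d$annual_death_probability)
}

#' @rdname calibration_io
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(
    data.frame(age_lower = table$age_lower, age_upper = table$age_upper,
               annual_death_probability = table$annual_death_prob),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_schedule <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("cycle_index", "probability") %in% names(d))) {
    stop(sprintf("%s: expected columns cycle_index, probability", path))
  }
  if (!identical(as.integer(d$cycle_index), seq_len(nrow(d)) - 1L)) {
    stop(sprintf("%s: cycle_index must run 0..%d without gaps", path, nrow(d) - 1L))
  }
  if (any(d$probability < 0 | d$probability > 1)) {
    stop(sprintf("%s: probabilities outside [0, 1]", path))
  }
  d$probability
}

#' @rdname calibration_io
#' @export
write_schedule <- function(probs, path) {
  utils::write.csv(
    data.frame(cycle_index = seq_along(probs) - 1L, probability = probs),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
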