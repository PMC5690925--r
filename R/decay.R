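# Cobalt-60 decay arithmetic linking nominal-planning beam-on times to
# day-of-treatment delivered times.

#' Co-60 half-life in years
#'
#' Default used wherever a configuration does not override it.
#' @export
CO60_HALF_LIFE_YEARS <- 5.2711

DAYS_PER_YEAR <- 365.25

#' Radioactive decay factor between two dates
#'
#' Fraction of source activity remaining after the elapsed time,
#' 2^(-dt / T1/2) with dt in years.
#'
#' @param calibration_date date the source strength was calibrated
#' @param query_date date to decay to; must not precede calibration
#' @param half_life_years half-life in years (default Co-60)
#' @return dimensionless factor in (0, 1]
#' @export
#' @examples
#' decay_factor(as.Date("2026-01-01"), as.Date("2026-01-01"))  # 1
decay_factor <- function(calibration_date, query_date,
                         half_life_years = CO60_HALF_LIFE_YEARS) {
  calibration_date <- as.Date(calibration_date)
  query_date <- as.Date(query_date)
  if (query_date < calibration_date)
    stop_invalid("query_date %s precedes calibration_date %s",
                 query_date, calibration_date)
  dt_years <- as.numeric(query_date - calibration_date) / DAYS_PER_YEAR
  decay_factor_elapsed(dt_years, half_life_years)
}

#' Decay factor for an elapsed time in years
#'
#' Closed form 2^(-dt / T1/2); [decay_factor()] is this on a date pair.
#' @param dt_years elapsed time, years (>= 0)
#' @param half_life_years half-life, years
#' @return dimensionless factor in (0, 1]
#' @export
decay_factor_elapsed <- function(dt_years,
                                 half_life_years = CO60_HALF_LIFE_YEARS) {
  if (any(dt_years < 0)) stop_invalid("elapsed time must be >= 0")
  if (!is.finite(half_life_years) || half_life_years <= 0)
    stop_invalid("half_life_years must be > 0")
  2^(-dt_years / half_life_years)
}

#' Expected as-delivered beam-on time for a planned time
#'
#' Planned times are defined at the nominal planning dose rate; the machine
#' delivers the same fluence at the day's decayed dose rate, so the
#' delivered time scales by nominal_rate / day_rate.
#'
#' @param planned_s planned beam-on time, seconds, at `nominal_rate`
#' @param nominal_rate planning dose rate, Gy/min
#' @param day_rate day-of-treatment decayed dose rate, Gy/min
#' @return expected delivered time, seconds
#' @export
expected_delivered_time <- function(planned_s, nominal_rate, day_rate) {
  if (!all(is.finite(c(nominal_rate, day_rate))) ||
      nominal_rate <= 0 || day_rate <= 0)
    stop_invalid("dose rates must be positive")
  planned_s * nominal_rate / day_rate
}

#' Put a delivered beam-on time back on the nominal planning scale
#'
#' Inverse of [expected_delivered_time()]; plan and log times can then be
#' compared directly, and fluence maps composed on a common scale.
#'
#' @inheritParams expected_delivered_time
#' @param delivered_s as-delivered time, seconds, at `day_rate`
#' @return equivalent time at `nominal_rate`, seconds
#' @export
normalize_delivered_time <- function(delivered_s, nominal_rate, day_rate) {
  if (!all(is.finite(c(nominal_rate, day_rate))) ||
      nominal_rate <= 0 || day_rate <= 0)
    stop_invalid("dose rates must be positive")
  delivered_s * day_rate / nominal_rate
}

#' Decay a reference source to a given date
#'
#' Returns a new [source_info()] whose decayed strength and dose rate are
#' the calibration values scaled by the decay factor to `query_date`.
#'
#' @param src a [source_info()] (its calibration fields are used)
#' @param query_date date to decay to
#' @param half_life_years half-life in years
#' @return a [source_info()] with `as_of_date = query_date`
#' @export
decay_source <- function(src, query_date,
                         half_life_years = CO60_HALF_LIFE_YEARS) {
  stopifnot(inherits(src, "source_info"))
  f <- decay_factor(src$calibration_date, query_date, half_life_years)
  source_info(src$head_id, src$serial, src$calibration_date,
              src$calibration_strength, src$calibration_dose_rate,
              src$calibration_strength * f, src$calibration_dose_rate * f,
              query_date)
}

#' Day-of-treatment dose rate of the head delivering a beam
#' @param sources list of 3 [source_info()] with decayed values as of the
#'   treatment day
#' @param head_id head 1..3
#' @return decayed dose rate, Gy/min
#' @export
head_day_rate <- function(sources, head_id) {
  heads <- vapply(sources, `[[`, integer(1), "head_id")
  i <- match(as.integer(head_id), heads)
  if (is.na(i)) stop_invalid("no source for head %s", head_id)
  sources[[i]]$decayed_dose_rate
}
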