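#' Long-term morbidity burden of an annual facial palsy cohort
#'
#' A recovery cohort is a tibble with one row per recovery state:
#' \describe{
#'   \item{state}{`"full"`, `"partial"` or `"permanent"`}
#'   \item{cases}{number of cases diagnosed per year entering the state}
#'   \item{duration_years}{time spent in the state. Full recovery defaults
#'     to 0.5 years (HRQoL affected for ~6 months); incomplete recovery
#'     lasts the remaining lifetime, see [lifetime_duration()].}
#' }
#'
#' @param state,cases,duration_years Column vectors, recycled.
#' @return A validated cohort tibble.
#' @examples
#' recovery_cohort(
#'   state = c("full", "partial", "permanent"),
#'   cases = c(16086, 2945, 3625),
#'   duration_years = c(0.5, 44.1, 44.1)
#' )
#' @export
recovery_cohort <- function(state, cases, duration_years) {
  cohort <- tibble::tibble(
    state = as.character(state),
    cases = as.numeric(cases),
    duration_years = as.numeric(duration_years)
  )
  if (any(cohort$cases < 0) || any(cohort$duration_years < 0)) {
    stop("cases and duration_years must be non-negative", call. = FALSE)
  }
  cohort
}

#' Remaining lifetime at diagnosis
#'
#' Years spent in an unresolved health state for a patient diagnosed at the
#' median age who lives to the national life expectancy.
#'
#' @param median_age_dx Median age at diagnosis, years (UK Bell palsy: 37.5).
#' @param life_expectancy Average length of life, years (UK: 81.6).
#' @return `life_expectancy - median_age_dx` in years (37.5, 81.6 -> 44.1).
#' @export
lifetime_duration <- function(median_age_dx, life_expectancy) {
  check_scalar_nonneg(median_age_dx, "median_age_dx")
  check_scalar_nonneg(life_expectancy, "life_expectancy")
  if (life_expectancy <= median_age_dx) {
    stop("life_expectancy must exceed median_age_dx", call. = FALSE)
  }
  life_expectancy - median_age_dx
}

#' QALY loss per recovery state
#'
#' cases x years-in-state x annual utility decrement, per state. The
#' decrement is the average reported HRQoL decrease while living with
#' facial palsy, applied uniformly to all states. An optional annual
#' discount rate hook is exposed; the default 0 reflects undiscounted
#' lifetime losses.
#'
#' @param cohort A recovery cohort tibble (see [recovery_cohort()]).
#' @param decrement Annual utility decrement in \eqn{[0, 1]}.
#' @param discount_rate Annual discount rate applied over each state's
#'   duration (default 0 = no discounting).
#' @return Cohort tibble with `qalys_lost` (full precision) and
#'   `qalys_lost_rounded` (half-up to whole QALYs, as presented in tables).
#' @examples
#' recovery_cohort("partial", 2945, 44.1) |> qaly_loss(0.04)
#' @export
qaly_loss <- function(cohort, decrement, discount_rate = 0) {
  if (!is.numeric(decrement) || length(decrement) != 1 ||
    decrement < 0 || decrement > 1) {
    stop("decrement must be a single value in [0, 1]", call. = FALSE)
  }
  check_scalar_nonneg(discount_rate, "discount_rate")
  dplyr::mutate(cohort,
    effective_years = if (discount_rate == 0) {
      .data$duration_years
    } else {
      # continuous-time annuity factor: integral of e^(-rt) over the stay
      (1 - exp(-discount_rate * .data$duration_years)) / discount_rate
    },
    qalys_lost = .data$cases * .data$effective_years * decrement,
    qalys_lost_rounded = round_half_up(.data$qalys_lost),
    effective_years = NULL
  )
}

#' Recover the utility decrement from a published QALY loss
#'
#' Algebraic inverse of [qaly_loss()] for a single state: the annual
#' decrement implied by a printed QALY-loss figure.
#'
#' @param qalys_lost Total QALYs lost in the state.
#' @param cases Cases in the state.
#' @param duration_years Years in the state.
#' @return `qalys_lost / (cases * duration_years)`.
#' @examples
#' calibrate_decrement(5195, 2945, 44.1) # ~0.04
#' @export
calibrate_decrement <- function(qalys_lost, cases, duration_years) {
  check_scalar_nonneg(qalys_lost, "qalys_lost")
  person_years <- cases * duration_years
  if (!is.finite(person_years) || person_years <= 0) {
    stop("cases * duration_years must be positive", call. = FALSE)
  }
  qalys_lost / person_years
}

#' Monetise QALY losses with a willingness-to-pay band
#'
#' Applies a cost-per-QALY threshold interval (default: the NICE band of
#' 20,000-30,000 GBP per QALY) to convert QALYs into a money interval.
#'
#' @param qalys QALYs (non-negative scalar).
#' @param wtp_low,wtp_high GBP per QALY bounds.
#' @return A [money_interval()] (`qalys * wtp_low`, `qalys * wtp_high`).
#' @examples
#' monetize_qalys(11912) # 238.24m - 357.36m
#' @export
monetize_qalys <- function(qalys, wtp_low = 20000, wtp_high = 30000) {
  check_scalar_nonneg(qalys, "qalys")
  check_scalar_nonneg(wtp_low, "wtp_low")
  if (wtp_high < wtp_low) stop("wtp_high must be >= wtp_low", call. = FALSE)
  money_interval(qalys * wtp_low, qalys * wtp_high)
}

#' Societal cost of unresolved cases
#'
#' Flat per-case interval (default: cumulative social security benefit
#' payments of 5,000-10,000 GBP over 5 years for comparable disablement)
#' scaled by the number of cases.
#'
#' @param cases Number of cases.
#' @param per_case_low,per_case_high GBP per case bounds.
#' @return A [money_interval()].
#' @examples
#' societal_cost(22657) # 113.285m - 226.57m
#' @export
societal_cost <- function(cases, per_case_low = 5000, per_case_high = 10000) {
  check_scalar_nonneg(cases, "cases")
  if (per_case_high < per_case_low) {
    stop("per_case_high must be >= per_case_low", call. = FALSE)
  }
  money_interval(cases * per_case_low, cases * per_case_high)
}

#' Total economic burden
#'
#' Component-wise sum of the monetised morbidity interval and the societal
#' cost interval.
#'
#' @param morbidity,societal Money intervals.
#' @return A [money_interval()].
#' @export
total_burden <- function(morbidity, societal) {
  interval_sum(morbidity, societal)
}

#' Full morbidity-burden table for a cohort
#'
#' Convenience pipeline: per-state QALY losses and their monetised
#' intervals, plus an all-cases total row. The total QALY figure is the sum
#' of per-state *rounded* losses, matching how published tables sum
#' independently rounded rows.
#'
#' @inheritParams qaly_loss
#' @inheritParams monetize_qalys
#' @return Tibble with one row per state plus a `"total"` row; columns
#'   `state, cases, duration_years, qalys_lost, qalys_lost_rounded,
#'   cost_low, cost_high`.
#' @export
burden_table <- function(cohort, decrement, wtp_low = 20000, wtp_high = 30000) {
  per_state <- qaly_loss(cohort, decrement) |>
    dplyr::mutate(
      cost_low = .data$qalys_lost_rounded * wtp_low,
      cost_high = .data$qalys_lost_rounded * wtp_high
    )
  total <- tibble::tibble(
    state = "total",
    cases = sum(per_state$cases),
    duration_years = NA_real_,
    qalys_lost = sum(per_state$qalys_lost),
    qalys_lost_rounded = sum(per_state$qalys_lost_rounded),
    cost_low = sum(per_state$qalys_lost_rounded) * wtp_low,
    cost_high = sum(per_state$qalys_lost_rounded) * wtp_high
  )
  dplyr::bind_rows(per_state, total)
}
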