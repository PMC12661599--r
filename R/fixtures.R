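#' Published UK facial palsy study inputs
#'
#' The complete set of inputs printed in the UK economic study of facial
#' palsy and smart-glasses telerehabilitation, as typed objects: the
#' 12-month treatment-cost ledger, the recovery cohort and burden
#' parameters, the Delphi consensus summary, the fNMR pathway cost
#' schedule, and the decision-model constants. Values are stored at the
#' precision the study printed them; several printed cells are internally
#' inconsistent with their own inputs (independently rounded cells) and
#' are kept under `printed` so that [reproduce_analysis()] can flag rather
#' than silently match them.
#'
#' @return A list with elements:
#' \describe{
#'   \item{treatment_ledger}{[cost_ledger()] of the 12-month treatment and
#'     therapy costs (2020/2021 prices).}
#'   \item{cohort}{[recovery_cohort()] of annual cases by recovery state.}
#'   \item{burden_params}{median age at diagnosis, life expectancy,
#'     published per-state QALY losses used to calibrate the utility
#'     decrement, NICE willingness-to-pay band, societal per-case band.}
#'   \item{delphi}{published consensus summary (agreement %, modal rating,
#'     round) plus panel counts.}
#'   \item{fnmr_schedule}{pathway cost schedule for a full fNMR course,
#'     with printed line totals.}
#'   \item{cea}{probability-weighted expected costs/effects of the two
#'     model arms, device price, cohort sizes, Delphi valuation of a
#'     high-grade recovery.}
#'   \item{printed}{headline figures exactly as printed, for
#'     computed-vs-printed checks.}
#' }
#' @examples
#' fx <- study_fixtures()
#' grand_total(fx$treatment_ledger) # ~86.98 million
#' @export
study_fixtures <- function() {
  treatment_ledger <- cost_ledger(
    activity = c(
      "GP consultations",
      "Corticosteroids/prednisolone",
      "Other medication (eg, antivirals, antibiotics)",
      "Referral to ophthalmologist",
      "Referral to ear, nose, and throat consultant",
      "Referral to plastic surgeon",
      "Referral to another specialist (eg, neurologist)",
      "Total elective inpatient episodes",
      "Initial consultations with facial therapist",
      "Follow-up appointments",
      "Acupuncture",
      "Electrical stimulation",
      "Massage, etc",
      "Counselling",
      "Cognitive behavioral therapy"
    ),
    volume = c(
      67971, 22657, 5664,
      6570, 6570, 3625, 2266,
      22457,
      1120, 2674,
      1133, 1133, 1133,
      1133, 1133
    ),
    unit_cost = c(
      39.00, 45.33, 15.41,
      123, 123, 122, 122,
      3573,
      53, 53,
      68.82, 38.16, 38.16,
      123, 122.16
    ),
    category = c(
      rep("medical/primary-care", 3),
      rep("medical/outpatient", 4),
      "medical/inpatient",
      rep("therapy/fnmr", 2),
      rep("therapy/physical", 3),
      rep("therapy/psychological", 2)
    ),
    price_year = "2020/2021"
  )

  cohort <- recovery_cohort(
    state = c("full", "partial", "permanent"),
    cases = c(16086, 2945, 3625),
    duration_years = c(0.5, 44.1, 44.1)
  )

  burden_params <- list(
    median_age_dx = 37.5,
    life_expectancy = 81.6,
    # published all-cases count; note the per-state rows sum to 22,656
    total_cases = 22657,
    # published per-state QALY losses; partial-recovery row used to
    # calibrate the (unpublished) annual utility decrement
    published_qalys = c(full = 322, partial = 5195, permanent = 6395),
    published_qalys_total = 11912,
    wtp_low = 20000, wtp_high = 30000,
    societal_per_case_low = 5000, societal_per_case_high = 10000
  )

  delphi <- list(
    summary = tibble::tibble(
      item = c(
        "High-grade paralysis (grades 5 and 6)",
        "Medium-grade paralysis (grades 3 and 4)",
        "Low-grade paralysis (grades 1 and 2)"
      ),
      agreement_pct = c(83, 69, 35),
      modal_rating = c(">=19400", ">=8600", "<=1800"),
      round_reached = c(1, 2, NA)
    ),
    threshold_pct = 66,
    invited = 26,
    round1_responded = 26,
    round2_responded = 19
  )

  fnmr_schedule <- tibble::tibble(
    activity = c(
      "Initial multidisciplinary team clinic appointment",
      "Psychological assessment",
      "fNMR appointments (with neurophysiotherapist)",
      "Botulinum toxin appointments"
    ),
    unit_cost = c(159.68, 95.72, 65.85, 247.57),
    units = c(1, 1, 6, 10),
    line_total = c(159.68, 95.72, 395.10, 2475.65)
  )

  cea <- list(
    with_frame = tibble::tibble(
      label = "with Frame", expected_cost = 1095.38, expected_effect = 1.261
    ),
    without_frame = tibble::tibble(
      label = "without Frame", expected_cost = 1563.07, expected_effect = 1.125
    ),
    device_price = 495.83,
    n_fnmr_referred = 1120,
    n_unresolved = 6570,
    hb_value_high_grade = 19400
  )

  printed <- list(
    grand_total_millions = 86.98,
    medical_total_millions = 86.339,
    primary_care_total = 3765300, # printed "3.7653 million"
    referral_total = 2334900, # printed "2.3349 million"
    therapy_total = 643292,
    inpatient_share_pct = 92.9,
    outpatient_share_pct = 2.7,
    primary_care_share_pct = 4.4,
    fnmr_share_of_therapy_pct = 31.3,
    lifetime_years = 44.1,
    qalys_by_state = c(full = 322, partial = 5195, permanent = 6395),
    qalys_total = 11912,
    morbidity_low_millions = 238.24,
    morbidity_high_millions = 357.31, # sum of independently rounded cells
    morbidity_cells_high_millions = c(full = 9.60, partial = 155.85, permanent = 191.86),
    societal_low_millions = 113.3,
    societal_high_millions = 226.6,
    total_burden_low_millions = 351,
    total_burden_high_millions = 584,
    fnmr_course_total = 3126.10, # line-item sum prints 3126.15
    incremental_cost = -467.69,
    incremental_effect = 0.14, # full precision 0.136
    break_even_price = 964,
    cohort_saving_fnmr_millions = 0.52,
    cohort_saving_all_millions = 3.08, # rounded-input product; exact is 3.0727
    health_gain_value_millions = 17.8,
    response_rate_round2_pct = 73.1,
    gbp_per_usd = 1.36
  )

  list(
    treatment_ledger = treatment_ledger,
    cohort = cohort,
    burden_params = burden_params,
    delphi = delphi,
    fnmr_schedule = fnmr_schedule,
    cea = cea,
    printed = printed
  )
}
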