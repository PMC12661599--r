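#' Re-run the full published analysis and check it against the printed figures
#'
#' Recomputes every headline figure of the UK facial palsy economic study
#' from the packaged inputs ([study_fixtures()]): budget-impact totals and
#' shares, morbidity QALY losses and their monetisation, societal and
#' total burden intervals, the cost-effectiveness incrementals with
#' dominance class, break-even device price, cohort-scaled savings,
#' health-gain valuation, and the Delphi summary. Each line is compared
#' with the printed figure at the precision the study printed it
#' (half-up). Figures known to be internally inconsistent in the source
#' tables (independently rounded cells) are *flagged*, not matched; they
#' do not count as failures.
#'
#' @param wtp Willingness to pay per QALY used for the net-monetary-benefit
#'   line (GBP; default 20000).
#' @return An object of class `fp_report`: list with `checks` (tibble:
#'   `section`, `quantity`, `computed`, `printed`, `digits`, `match`,
#'   `flag`), `dominance` (character), and `ok` (TRUE when every unflagged
#'   check matches).
#' @examples
#' rep <- reproduce_analysis()
#' rep$ok
#' rep$dominance
#' @export
reproduce_analysis <- function(wtp = 20000) {
  fx <- study_fixtures()
  pr <- fx$printed
  rows <- list()
  check <- function(section, quantity, computed, printed, digits = 0,
                    flag = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      section = section, quantity = quantity,
      computed = computed, printed = printed, digits = digits,
      match = is.na(flag) &
        abs(round_half_up(computed, digits) - printed) < 10^(-digits) / 2,
      flag = flag
    )
  }

  # --- budget impact (12-month treatment ledger) ---
  led <- fx$treatment_ledger
  check("budget", "grand_total_millions", gbp_millions(grand_total(led)),
    pr$grand_total_millions,
    digits = 2
  )
  check("budget", "medical_total_millions",
    gbp_millions(subtotal(led, "medical"), 3), pr$medical_total_millions,
    digits = 3
  )
  check("budget", "primary_care_total",
    subtotal(led, "medical/primary-care"), pr$primary_care_total,
    flag = paste(
      "printed 3.7653 million is the sum of independently rounded cells;",
      "volume x unit_cost gives 3.7652 million"
    )
  )
  check("budget", "referral_total", subtotal(led, "medical/outpatient"),
    pr$referral_total,
    digits = -2
  )
  check("budget", "therapy_total", subtotal(led, "therapy"), pr$therapy_total)
  check("budget", "inpatient_share_pct",
    category_share(led, "medical/inpatient", "medical"),
    pr$inpatient_share_pct,
    digits = 1
  )
  check("budget", "outpatient_share_pct",
    category_share(led, "medical/outpatient", "medical"),
    pr$outpatient_share_pct,
    digits = 1
  )
  check("budget", "primary_care_share_pct",
    category_share(led, "medical/primary-care", "medical"),
    pr$primary_care_share_pct,
    digits = 1
  )
  check("budget", "fnmr_share_of_therapy_pct",
    category_share(led, "therapy/fnmr", "therapy"),
    pr$fnmr_share_of_therapy_pct,
    digits = 1
  )

  # --- long-term morbidity burden ---
  bp <- fx$burden_params
  years <- lifetime_duration(bp$median_age_dx, bp$life_expectancy)
  check("burden", "lifetime_years", years, pr$lifetime_years, digits = 1)
  partial <- fx$cohort[fx$cohort$state == "partial", ]
  decrement <- calibrate_decrement(
    bp$published_qalys[["partial"]], partial$cases, partial$duration_years
  )
  bt <- burden_table(fx$cohort, decrement, bp$wtp_low, bp$wtp_high)
  for (st in c("full", "partial", "permanent")) {
    check("burden", paste0("qalys_", st),
      bt$qalys_lost_rounded[bt$state == st], pr$qalys_by_state[[st]])
  }
  total_qalys <- bt$qalys_lost_rounded[bt$state == "total"]
  check("burden", "qalys_total", total_qalys, pr$qalys_total)
  morbidity <- monetize_qalys(total_qalys, bp$wtp_low, bp$wtp_high)
  check("burden", "morbidity_low_millions", gbp_millions(morbidity$low),
    pr$morbidity_low_millions,
    digits = 2
  )
  check("burden", "morbidity_high_millions", gbp_millions(morbidity$high),
    pr$morbidity_high_millions,
    digits = 2,
    flag = paste(
      "printed 357.31 sums independently rounded cells (9.60 + 155.85 +",
      "191.86); 11,912 QALYs x 30,000 gives 357.36"
    )
  )
  check("burden", "morbidity_cell_full_high_millions",
    gbp_millions(bt$cost_high[bt$state == "full"]),
    pr$morbidity_cells_high_millions[["full"]],
    digits = 2,
    flag = "printed 9.60 vs computed 322 x 30,000 = 9.66 million"
  )
  check("burden", "morbidity_cell_permanent_high_millions",
    gbp_millions(bt$cost_high[bt$state == "permanent"]),
    pr$morbidity_cells_high_millions[["permanent"]],
    digits = 2,
    flag = "printed 191.86 vs computed 6395 x 30,000 = 191.85 million"
  )
  soc <- societal_cost(
    bp$total_cases,
    bp$societal_per_case_low, bp$societal_per_case_high
  )
  check("burden", "societal_low_millions", gbp_millions(soc$low, 1),
    pr$societal_low_millions,
    digits = 1
  )
  check("burden", "societal_high_millions", gbp_millions(soc$high, 1),
    pr$societal_high_millions,
    digits = 1
  )
  burden <- total_burden(morbidity, soc)
  check("burden", "total_burden_low_millions", gbp_millions(burden$low, 0),
    pr$total_burden_low_millions,
    flag = "printed 351 vs computed 238.24m + 113.285m = 351.5m (rounds to 352)"
  )
  check("burden", "total_burden_high_millions", gbp_millions(burden$high, 0),
    pr$total_burden_high_millions
  )

  # --- cost-effectiveness of the telerehabilitation pathway ---
  check("cea", "fnmr_course_total",
    sum(pathway_table(fx$fnmr_schedule)$line_value), pr$fnmr_course_total,
    digits = 2,
    flag = "printed total 3126.10 vs sum of its printed line values 3126.15"
  )
  cea <- compare_strategies(fx$cea$with_frame, fx$cea$without_frame, wtp = wtp)
  check("cea", "incremental_cost", cea$delta_cost, pr$incremental_cost,
    digits = 2
  )
  check("cea", "incremental_effect", cea$delta_effect, pr$incremental_effect,
    digits = 2
  )
  be <- break_even_price(fx$cea$device_price, cea$delta_cost)
  check("cea", "break_even_price", be, pr$break_even_price)
  check("cea", "cohort_saving_fnmr_millions",
    gbp_millions(cohort_scale(-cea$delta_cost, fx$cea$n_fnmr_referred)),
    pr$cohort_saving_fnmr_millions,
    digits = 2
  )
  check("cea", "cohort_saving_all_millions",
    gbp_millions(cohort_scale(-cea$delta_cost, fx$cea$n_unresolved)),
    pr$cohort_saving_all_millions,
    digits = 2,
    flag = paste(
      "printed 3.08m apparently uses unrounded per-patient savings;",
      "467.69 x 6570 = 3.07m"
    )
  )
  check("cea", "health_gain_value_millions",
    gbp_millions(value_health_gain(
      round_half_up(cea$delta_effect, 2),
      fx$cea$hb_value_high_grade, fx$cea$n_unresolved
    ), 1),
    pr$health_gain_value_millions,
    digits = 1
  )

  # --- Delphi consensus ---
  dl <- fx$delphi
  check("delphi", "response_rate_round2_pct",
    response_rate(dl$invited, dl$round2_responded),
    pr$response_rate_round2_pct,
    digits = 1
  )
  for (i in seq_len(nrow(dl$summary))) {
    row <- dl$summary[i, ]
    check("delphi", paste0("consensus_item", i),
      as.numeric(consensus_check(row$agreement_pct, dl$threshold_pct)),
      as.numeric(!is.na(row$round_reached))
    )
  }

  checks <- dplyr::bind_rows(rows)
  structure(
    list(
      checks = checks,
      dominance = cea$dominance,
      nmb = cea$nmb,
      ok = all(checks$match | !is.na(checks$flag))
    ),
    class = "fp_report"
  )
}

#' @export
print.fp_report <- function(x, ...) {
  cat("Reproduction report:", nrow(x$checks), "checks;",
    sum(x$checks$match), "matched at printed precision;",
    sum(!is.na(x$checks$flag)), "flagged source-table inconsistencies\n"
  )
  cat("dominance class of the telerehabilitation arm:", x$dominance, "\n")
  cat("all unflagged checks pass:", x$ok, "\n")
  print(x$checks, n = nrow(x$checks))
  invisible(x)
}

#' Tidy a reproduction report
#'
#' @param x An `fp_report`.
#' @param ... Unused.
#' @return The checks tibble.
#' @exportS3Method generics::tidy
tidy.fp_report <- function(x, ...) {
  x$checks
}

#' Glance at a reproduction report
#'
#' @param x An `fp_report`.
#' @param ... Unused.
#' @return One-row tibble: check counts, dominance class, overall status.
#' @exportS3Method generics::glance
glance.fp_report <- function(x, ...) {
  tibble::tibble(
    n_checks = nrow(x$checks),
    n_matched = sum(x$checks$match),
    n_flagged = sum(!is.na(x$checks$flag)),
    dominance = x$dominance,
    ok = x$ok
  )
}

#' Render results to CSV, JSON and plain text
#'
#' Writes the same content in three formats: `<stem>.csv` (the tabular
#' result), `<stem>.json` (lossless record-per-row JSON, with report
#' metadata when given an `fp_report`), and `<stem>.txt` (human-readable
#' table).
#'
#' @param results An `fp_report` or any data frame.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"report"`).
#' @return Invisibly, the named vector of paths written.
#' @export
render_report <- function(results, dir, stem = "report") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  meta <- NULL
  if (inherits(results, "fp_report")) {
    meta <- list(dominance = results$dominance, ok = results$ok)
    results <- results$checks
  }
  stopifnot(is.data.frame(results))
  paths <- c(
    csv = file.path(dir, paste0(stem, ".csv")),
    json = file.path(dir, paste0(stem, ".json")),
    txt = file.path(dir, paste0(stem, ".txt"))
  )
  readr::write_csv(results, paths[["csv"]], na = "")
  payload <- list(rows = results)
  if (!is.null(meta)) payload <- c(meta, payload)
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output({
    if (!is.null(meta)) {
      cat("dominance:", meta$dominance, "| ok:", meta$ok, "\n\n")
    }
    print(as.data.frame(results), row.names = FALSE)
  })
  writeLines(txt, paths[["txt"]])
  invisible(paths)
}
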