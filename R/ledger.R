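#' Budget-impact cost ledgers
#'
#' A cost ledger is a tibble of annual activity line items, one row per
#' activity, with columns:
#' \describe{
#'   \item{activity}{free-text label, e.g. "GP consultations"}
#'   \item{volume}{annual number of cases/events (non-negative)}
#'   \item{unit_cost}{GBP per event at the stated price year}
#'   \item{category}{slash-delimited hierarchical path, e.g.
#'     `"medical/primary-care"` or `"therapy/fnmr"`}
#'   \item{price_year}{financial-year tag, e.g. `"2020/2021"`}
#' }
#' Totals are aggregated by matching category *prefixes*, which reproduces
#' two-level table subtotals (total primary care, total therapy, ...) without
#' a separate grouping schema.
#'
#' @param activity,volume,unit_cost,category,price_year Column vectors,
#'   recycled to a common length.
#' @return A validated ledger tibble.
#' @examples
#' cost_ledger(
#'   activity = "GP consultations", volume = 67971,
#'   unit_cost = 39, category = "medical/primary-care"
#' )
#' @export
cost_ledger <- function(activity, volume, unit_cost, category,
                        price_year = "2020/2021") {
  ledger <- tibble::tibble(
    activity = as.character(activity),
    volume = as.numeric(volume),
    unit_cost = as.numeric(unit_cost),
    category = as.character(category),
    price_year = as.character(price_year)
  )
  validate_ledger(ledger)
}

#' Validate a cost ledger
#'
#' Checks the ledger invariants: required columns present, volumes and unit
#' costs non-negative, category paths non-empty.
#'
#' @param ledger A ledger tibble (see [cost_ledger()]).
#' @return The ledger, invisibly usable in a pipe; errors on violation.
#' @export
validate_ledger <- function(ledger) {
  req <- c("activity", "volume", "unit_cost", "category")
  missing_cols <- setdiff(req, names(ledger))
  if (length(missing_cols) > 0) {
    stop("ledger is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(ledger$volume)) || any(ledger$volume < 0)) {
    stop("ledger volumes must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(ledger$unit_cost)) || any(ledger$unit_cost < 0)) {
    stop("ledger unit costs must be non-negative", call. = FALSE)
  }
  if (any(is.na(ledger$category) | ledger$category == "")) {
    stop("ledger category paths must be non-empty", call. = FALSE)
  }
  tibble::as_tibble(ledger)
}

#' Annual cost of each line item
#'
#' Volume times unit cost, carried at full precision; rounding happens only
#' at presentation.
#'
#' @param ledger A cost ledger.
#' @return The ledger with a `total_cost` column appended.
#' @examples
#' cost_ledger("GP consultations", 67971, 39, "medical/primary-care") |>
#'   line_item_cost()
#' @export
line_item_cost <- function(ledger) {
  validate_ledger(ledger)
  dplyr::mutate(tibble::as_tibble(ledger),
    total_cost = .data$volume * .data$unit_cost
  )
}

#' Re-index costs with a cost inflation index
#'
#' Adjusts GBP amounts between financial years using an index series such as
#' the NHS Cost Inflation Index (pay and prices). The index is user-supplied
#' data: a named numeric vector or two-column data frame
#' (`year`, `index`) of positive index values.
#'
#' @param cost GBP amount(s) at `from_year` prices.
#' @param from_year,to_year Financial-year tags present in the index.
#' @param index Named numeric vector (`names` = years) or data frame with
#'   columns `year` and `index`.
#' @return `cost * index[to_year] / index[from_year]`.
#' @examples
#' idx <- c("2019/2020" = 1.00, "2020/2021" = 1.05)
#' inflate_cost(100, "2019/2020", "2020/2021", idx) # 105
#' @export
inflate_cost <- function(cost, from_year, to_year, index) {
  if (is.data.frame(index)) {
    stopifnot(all(c("year", "index") %in% names(index)))
    index <- stats::setNames(index$index, index$year)
  }
  stopifnot(is.numeric(index), !is.null(names(index)))
  if (any(index <= 0)) stop("inflation index values must be positive", call. = FALSE)
  for (yr in c(from_year, to_year)) {
    if (!yr %in% names(index)) {
      stop(sprintf("year '%s' not present in inflation index", yr), call. = FALSE)
    }
  }
  cost * unname(index[to_year] / index[from_year])
}

#' Category subtotal of a ledger
#'
#' Sums line-item costs over items whose category path starts with
#' `category_prefix`. An empty match returns 0; an empty prefix matches all
#' rows (the grand total).
#'
#' @param ledger A cost ledger.
#' @param category_prefix Slash-path prefix, e.g. `"medical/primary-care"`.
#' @return GBP subtotal (length-1 numeric), unrounded.
#' @export
subtotal <- function(ledger, category_prefix = "") {
  costed <- line_item_cost(ledger)
  hit <- startsWith(costed$category, category_prefix)
  sum(costed$total_cost[hit])
}

#' Grand total of a ledger
#'
#' Sum over all line items; equals the sum of subtotals over any exhaustive,
#' disjoint category partition.
#'
#' @param ledger A cost ledger.
#' @return GBP total (length-1 numeric), unrounded.
#' @export
grand_total <- function(ledger) {
  subtotal(ledger, "")
}

#' Percentage share of a category within another
#'
#' Used for statements such as "92.9% of medical costs are hospital
#' inpatient stays". Computed at full precision; round at report time
#' (1 decimal place, half-up) with [round_half_up()].
#'
#' @param ledger A cost ledger.
#' @param category_prefix Numerator category prefix.
#' @param within_prefix Denominator category prefix (default: whole ledger).
#' @return Percentage in \eqn{[0, 100]} (unrounded).
#' @export
category_share <- function(ledger, category_prefix, within_prefix = "") {
  denom <- subtotal(ledger, within_prefix)
  if (denom <= 0) {
    stop("denominator subtotal must be positive for a share", call. = FALSE)
  }
  100 * subtotal(ledger, category_prefix) / denom
}

#' Summarise a ledger by top-level category
#'
#' @param ledger A cost ledger.
#' @param depth How many slash-separated levels to keep when grouping.
#' @return Tibble with `category`, `total_cost` and `share_pct` (share of the
#'   grand total, unrounded).
#' @export
ledger_summary <- function(ledger, depth = 1) {
  costed <- line_item_cost(ledger)
  total <- sum(costed$total_cost)
  costed |>
    dplyr::mutate(category = vapply(
      strsplit(.data$category, "/", fixed = TRUE),
      function(parts) paste(utils::head(parts, depth), collapse = "/"),
      character(1)
    )) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(total_cost = sum(.data$total_cost), .groups = "drop") |>
    dplyr::mutate(share_pct = 100 * .data$total_cost / total)
}

#' Read / write a cost ledger as CSV
#'
#' CSV with header row and columns `activity, volume, unit_cost, category,
#' price_year` (UTF-8).
#'
#' @param path File path.
#' @return `read_ledger()` returns a validated ledger tibble;
#'   `write_ledger()` returns `path` invisibly.
#' @export
read_ledger <- function(path) {
  ledger <- readr::read_csv(path,
    col_types = readr::cols(
      activity = readr::col_character(),
      volume = readr::col_double(),
      unit_cost = readr::col_double(),
      category = readr::col_character(),
      price_year = readr::col_character()
    )
  )
  validate_ledger(ledger)
}

#' @rdname read_ledger
#' @param ledger A cost ledger.
#' @export
write_ledger <- function(ledger, path) {
  validate_ledger(ledger)
  readr::write_csv(ledger, path)
  invisible(path)
}
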