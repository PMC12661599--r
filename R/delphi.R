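#' Delphi modal-consensus analytics
#'
#' Ratings are held long format: one row per (round, panelist, item) with a
#' `rating` column holding the chosen category — an ordinal importance
#' level or a banded monetary range, treated as a plain category either
#' way (no interpolation within bands). Missing ratings (`NA`) are allowed
#' and excluded from agreement denominators: agreement is computed over the
#' panelists who responded to that item in that round, not the invited
#' panel.
#'
#' @name delphi
NULL

#' Modal rating and percentage agreement for one item
#'
#' The modal consensus approach: agreement is the share of non-missing
#' ratings falling on the modal category. When two or more categories tie
#' for the mode there is no unique mode; the item is flagged multimodal
#' and cannot reach consensus.
#'
#' @param ratings Vector of category ratings for one item (character or
#'   factor; `NA` = no response).
#' @return One-row tibble: `modal_rating` (NA if multimodal),
#'   `agreement_pct` (0-100, share at the mode), `n_responses`,
#'   `multimodal`.
#' @examples
#' modal_agreement(c(rep("A", 13), rep("B", 6))) # 68.4% at "A"
#' @export
modal_agreement <- function(ratings) {
  ratings <- as.character(ratings)
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) == 0) {
    stop("cannot score an item with no non-missing ratings", call. = FALSE)
  }
  counts <- table(ratings)
  top <- max(counts)
  modes <- names(counts)[counts == top]
  multimodal <- length(modes) > 1
  tibble::tibble(
    modal_rating = if (multimodal) NA_character_ else modes,
    agreement_pct = 100 * top / length(ratings),
    n_responses = length(ratings),
    multimodal = multimodal
  )
}

#' Consensus decision at an ex-ante threshold
#'
#' @param agreement_pct Percentage agreement at the modal rating (0-100).
#' @param threshold_pct Ex-ante consensus threshold (default 66). The
#'   boundary is inclusive: agreement equal to the threshold is consensus.
#' @return Logical.
#' @examples
#' consensus_check(83) # TRUE
#' consensus_check(35) # FALSE
#' @export
consensus_check <- function(agreement_pct, threshold_pct = 66) {
  stopifnot(
    is.numeric(agreement_pct), all(agreement_pct >= 0 & agreement_pct <= 100),
    is.numeric(threshold_pct), length(threshold_pct) == 1,
    threshold_pct >= 0, threshold_pct <= 100
  )
  agreement_pct >= threshold_pct
}

#' Score a multi-round Delphi exercise
#'
#' Items are scored round by round; an item that reaches consensus in
#' round r is extracted and not re-scored in later rounds (its result
#' carries forward). Items never reaching the threshold are reported with
#' their final-round agreement and `round_reached = NA`. Multimodal items
#' cannot reach consensus in that round.
#'
#' @param ratings Long tibble with columns `round` (sortable round id),
#'   `panelist`, `item`, `rating` (`NA` = no response).
#' @param threshold_pct Ex-ante consensus threshold (default 66).
#' @return Tibble, one row per item: `item`, `modal_rating`,
#'   `agreement_pct`, `consensus`, `round_reached` (NA when never
#'   reached), `multimodal`.
#' @examples
#' ratings <- tibble::tibble(
#'   round = rep(1, 4), panelist = paste0("p", 1:4),
#'   item = "outcome", rating = c("high", "high", "high", "low")
#' )
#' run_rounds(ratings)
#' @export
run_rounds <- function(ratings, threshold_pct = 66) {
  req <- c("round", "panelist", "item", "rating")
  stopifnot(all(req %in% names(ratings)))
  rounds <- sort(unique(ratings$round))
  all_items <- unique(ratings$item[ratings$round == rounds[1]])
  for (r in rounds[-1]) {
    round_items <- unique(ratings$item[ratings$round == r])
    extra <- setdiff(round_items, all_items)
    if (length(extra) > 0) {
      stop("round ", r, " introduces items absent from round 1: ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
  }
  results <- stats::setNames(vector("list", length(all_items)), all_items)
  for (r in rounds) {
    open_items <- all_items[vapply(all_items, function(it) {
      is.null(results[[it]]) || !results[[it]]$consensus
    }, logical(1))]
    this_round <- ratings[ratings$round == r & ratings$item %in% open_items, ]
    for (it in unique(this_round$item)) {
      item_ratings <- this_round$rating[this_round$item == it]
      if (all(is.na(item_ratings))) next
      scored <- modal_agreement(item_ratings)
      reached <- !scored$multimodal &&
        consensus_check(scored$agreement_pct, threshold_pct)
      results[[it]] <- dplyr::mutate(scored,
        item = it,
        consensus = reached,
        round_reached = if (reached) r else NA
      )
    }
  }
  unscored <- all_items[vapply(all_items, function(it) is.null(results[[it]]), logical(1))]
  if (length(unscored) > 0) {
    stop("items with no non-missing ratings in any round: ",
      paste(unscored, collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::bind_rows(results)[, c(
    "item", "modal_rating", "agreement_pct", "consensus",
    "round_reached", "multimodal", "n_responses"
  )]
}

#' Panel response rate
#'
#' @param invited Number of panelists invited (> 0).
#' @param responded Number who responded (`<= invited`).
#' @return Percentage at full precision; round with
#'   `round_half_up(x, 1)` for presentation (19/26 -> 73.1).
#' @export
response_rate <- function(invited, responded) {
  check_scalar_nonneg(invited, "invited")
  check_scalar_nonneg(responded, "responded")
  if (invited == 0) stop("invited must be positive", call. = FALSE)
  if (responded > invited) stop("responded cannot exceed invited", call. = FALSE)
  100 * responded / invited
}
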