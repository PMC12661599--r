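#' Seeded synthetic-data generators
#'
#' Each generator is a pure function of its arguments: the same seed gives
#' bit-identical output, and each generator draws from its own substream
#' (derived from the seed and the generator's name) so adding a generator
#' never perturbs another's output. Generated objects always satisfy the
#' invariants of the type they emulate.
#'
#' @name synth
NULL

# derive an independent, reproducible substream seed per generator
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (abs(as.integer(seed)) * 7919L + as.integer(h)) %% 2147483647L
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

#' Generate a synthetic cost ledger
#'
#' Multi-category annual cost ledger with lognormal unit costs (heavy
#' right tail, like reference-cost schedules) and uniform integer volumes,
#' spread over a two-level category hierarchy.
#'
#' @param n_items Number of line items.
#' @param seed Integer seed.
#' @param unit_cost_meanlog,unit_cost_sdlog Lognormal parameters for unit
#'   costs (defaults centre costs near 100 GBP with a long tail).
#' @param volume_range Integer range for annual volumes.
#' @param categories Top-level category labels; each item lands in a
#'   random `top/sub` path with `fanout` subcategories per top level.
#' @param fanout Subcategories per top-level category.
#' @return A validated cost ledger tibble.
#' @examples
#' gen_ledger(5, seed = 1)
#' @export
gen_ledger <- function(n_items = 10, seed = 1,
                       unit_cost_meanlog = log(100), unit_cost_sdlog = 1,
                       volume_range = c(10, 50000),
                       categories = c("medical", "therapy"), fanout = 3) {
  stopifnot(n_items >= 0, fanout >= 1, length(categories) >= 1)
  with_substream(seed, "ledger", {
    tops <- sample(categories, n_items, replace = TRUE)
    subs <- sample(paste0("sub", seq_len(fanout)), n_items, replace = TRUE)
    cost_ledger(
      activity = paste0("activity_", seq_len(n_items)),
      volume = if (n_items > 0) {
        sample(volume_range[1]:volume_range[2], n_items, replace = TRUE)
      } else {
        integer()
      },
      unit_cost = round(stats::rlnorm(n_items, unit_cost_meanlog, unit_cost_sdlog), 2),
      category = if (n_items > 0) paste(tops, subs, sep = "/") else character(),
      price_year = "2020/2021"
    )
  })
}

#' Generate a paired two-strategy decision tree
#'
#' Emulates the telerehabilitation model's shape: each arm splits into
#' recovery / no-recovery, and the recovery branch splits over three
#' severity strata (severe, moderate, mild) with stratum-specific payoffs.
#' The two arms share structure and payoffs; the intervention arm's
#' recovery probability is uplifted by `recovery_uplift` (capped at 1) and
#' it carries the device as an upfront per-entrant cost.
#'
#' @param seed Integer seed.
#' @param base_recovery Comparator's probability of some/full recovery;
#'   drawn uniformly from `c(0.3, 0.7)` range when `NULL`.
#' @param recovery_uplift Added recovery probability in the intervention
#'   arm (>= 0).
#' @param device_cost Upfront device cost in the intervention arm, GBP.
#' @param cost_range,effect_range Ranges for terminal costs (GBP) and
#'   effects (HB-grade gain) per severity stratum.
#' @return Named list of two `fp_strategy` objects:
#'   `intervention`, `comparator`.
#' @examples
#' arms <- gen_tree(seed = 1, recovery_uplift = 0.1, device_cost = 0)
#' compare_strategies(arms$intervention, arms$comparator)$dominance
#' @export
gen_tree <- function(seed = 1, base_recovery = NULL, recovery_uplift = 0.1,
                     device_cost = 495.83,
                     cost_range = c(500, 3500), effect_range = c(0, 3)) {
  stopifnot(recovery_uplift >= 0, device_cost >= 0)
  with_substream(seed, "tree", {
    if (is.null(base_recovery)) base_recovery <- stats::runif(1, 0.3, 0.7)
    stopifnot(base_recovery >= 0, base_recovery <= 1)
    severity_probs <- as.numeric(prop.table(stats::runif(3, 0.2, 1)))
    strata <- lapply(seq_len(3), function(i) {
      list(
        p = severity_probs[i],
        cost = stats::runif(1, cost_range[1], cost_range[2]),
        effect = stats::runif(1, effect_range[1], effect_range[2])
      )
    })
    no_recovery_cost <- stats::runif(1, cost_range[1], cost_range[2])
    build_arm <- function(label, p_recover, upfront) {
      recovery_subtree <- chance_node(lapply(strata, function(s) {
        branch(s$p, terminal_node(cost = s$cost, effect = s$effect))
      }))
      strategy(
        label,
        chance_node(
          branch(p_recover, recovery_subtree),
          branch(1 - p_recover, terminal_node(cost = no_recovery_cost, effect = 0))
        ),
        upfront_cost = upfront
      )
    }
    list(
      intervention = build_arm(
        "intervention",
        min(1, base_recovery + recovery_uplift), device_cost
      ),
      comparator = build_arm("comparator", base_recovery, 0)
    )
  })
}

#' Generate a synthetic Delphi rating matrix
#'
#' Each panelist-item rating falls on the item's designated modal category
#' with probability `modal_concentration`, and uniformly on the remaining
#' categories otherwise; responses are missing independently at
#' `missing_rate`. As the panel grows, expected agreement at the mode
#' approaches `100 * modal_concentration` (plus the uniform remainder's
#' small contribution).
#'
#' @param n_panelists,n_items Panel dimensions.
#' @param modal_concentration Probability of the modal category, in
#'   \eqn{[0, 1]}.
#' @param missing_rate Independent missingness probability, in
#'   \eqn{[0, 1)}.
#' @param categories Rating categories; the first is the designated mode
#'   for every item.
#' @param round_id Round identifier attached to every row.
#' @param seed Integer seed.
#' @return Long ratings tibble (`round`, `panelist`, `item`, `rating`)
#'   suitable for [run_rounds()].
#' @examples
#' gen_panel(n_panelists = 4, n_items = 2, modal_concentration = 1, seed = 1)
#' @export
gen_panel <- function(n_panelists = 19, n_items = 3,
                      modal_concentration = 0.8, missing_rate = 0,
                      categories = c(">=19400", ">=8600", "<=1800"),
                      round_id = 1, seed = 1) {
  stopifnot(
    modal_concentration >= 0, modal_concentration <= 1,
    missing_rate >= 0, missing_rate < 1, length(categories) >= 2
  )
  with_substream(seed, "panel", {
    grid <- tidyr::expand_grid(
      panelist = paste0("panelist_", seq_len(n_panelists)),
      item = paste0("item_", seq_len(n_items))
    )
    n <- nrow(grid)
    on_mode <- stats::runif(n) < modal_concentration
    others <- sample(categories[-1], n, replace = TRUE)
    rating <- ifelse(on_mode, categories[1], others)
    rating[stats::runif(n) < missing_rate] <- NA_character_
    dplyr::mutate(grid, round = round_id, rating = rating)[
      , c("round", "panelist", "item", "rating")
    ]
  })
}
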