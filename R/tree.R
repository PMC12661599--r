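#' Decision-tree building blocks
#'
#' A strategy (model arm) is a finite, acyclic tree of chance nodes ending
#' in terminal nodes. Terminal payoffs carry a pathway cost in GBP and a
#' health effect measured as House-Brackmann (HB) grade improvement; branch
#' probabilities at each chance node must sum to one. Device or other
#' per-entrant costs sit in the strategy's `upfront_cost`.
#'
#' @param cost Terminal pathway cost, GBP (non-negative).
#' @param effect Terminal health effect, HB-grade improvement (non-negative).
#' @return `terminal_node()` / `chance_node()` return node lists;
#'   `strategy()` returns an object of class `fp_strategy`.
#' @examples
#' arm <- strategy(
#'   "with device",
#'   chance_node(
#'     branch(0.7, terminal_node(cost = 1000, effect = 1.5)),
#'     branch(0.3, terminal_node(cost = 1800, effect = 0))
#'   ),
#'   upfront_cost = 495.83
#' )
#' rollback(arm)
#' @export
terminal_node <- function(cost, effect) {
  check_scalar_nonneg(cost, "cost")
  check_scalar_nonneg(effect, "effect")
  structure(list(type = "terminal", cost = cost, effect = effect),
    class = "fp_node"
  )
}

#' @rdname terminal_node
#' @param ... For `chance_node()`: branches created with [branch()].
#' @export
chance_node <- function(...) {
  branches <- list(...)
  if (length(branches) == 1 && is.list(branches[[1]]) &&
    is.null(branches[[1]]$p)) {
    branches <- branches[[1]] # allow a pre-built list of branches
  }
  structure(list(type = "chance", branches = branches), class = "fp_node")
}

#' @rdname terminal_node
#' @param p Branch probability in \eqn{[0, 1]}.
#' @param node Child node.
#' @export
branch <- function(p, node) {
  list(p = p, node = node)
}

#' @rdname terminal_node
#' @param label Strategy label, e.g. `"with Frame"`.
#' @param root Root node of the tree.
#' @param upfront_cost GBP applied to every entrant (e.g. a single-use
#'   device price in the telerehabilitation arm). Default 0.
#' @export
strategy <- function(label, root, upfront_cost = 0) {
  check_scalar_nonneg(upfront_cost, "upfront_cost")
  structure(
    list(label = label, root = root, upfront_cost = upfront_cost),
    class = "fp_strategy"
  )
}

#' Validate a strategy's decision tree
#'
#' Walks the tree and collects every violated constraint: branch
#' probabilities outside \eqn{[0, 1]} or not summing to one (tolerance
#' 1e-9), chance nodes without branches, terminal nodes with missing or
#' negative payoffs, unknown node types, and depth beyond `max_depth`
#' (guards against malformed self-referencing input).
#'
#' @param strat An `fp_strategy`.
#' @param max_depth Maximum permitted tree depth.
#' @return A tibble with columns `node_path` and `problem`, one row per
#'   violation (zero rows when valid), with attribute `valid`.
#' @examples
#' ok <- strategy("a", chance_node(
#'   branch(0.6, terminal_node(10, 1)),
#'   branch(0.4, terminal_node(20, 0))
#' ))
#' validate_tree(ok)
#' @export
validate_tree <- function(strat, max_depth = 64) {
  stopifnot(inherits(strat, "fp_strategy"))
  issues <- list()
  note <- function(path, problem) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      node_path = path, problem = problem
    )
  }
  walk <- function(node, path, depth) {
    if (depth > max_depth) {
      note(path, sprintf("depth exceeds %d (cycle or malformed tree?)", max_depth))
      return(invisible(NULL))
    }
    if (!is.list(node) || is.null(node$type)) {
      note(path, "node has no type")
      return(invisible(NULL))
    }
    if (node$type == "terminal") {
      for (field in c("cost", "effect")) {
        v <- node[[field]]
        if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
          note(path, sprintf("terminal %s missing or non-numeric", field))
        } else if (v < 0) {
          note(path, sprintf("terminal %s is negative", field))
        }
      }
    } else if (node$type == "chance") {
      if (length(node$branches) == 0) {
        note(path, "chance node has no branches")
        return(invisible(NULL))
      }
      probs <- vapply(node$branches, function(b) {
        if (is.null(b$p) || !is.numeric(b$p)) NA_real_ else as.numeric(b$p)
      }, numeric(1))
      if (any(is.na(probs))) {
        note(path, "branch probability missing or non-numeric")
      } else {
        if (any(probs < 0 | probs > 1)) {
          note(path, "branch probability outside [0, 1]")
        }
        if (abs(sum(probs) - 1) > 1e-9) {
          note(path, sprintf("branch probabilities sum to %.12f, not 1", sum(probs)))
        }
      }
      for (i in seq_along(node$branches)) {
        walk(node$branches[[i]]$node, paste0(path, "/", i), depth + 1)
      }
    } else {
      note(path, sprintf("unknown node type '%s'", node$type))
    }
    invisible(NULL)
  }
  walk(strat$root, "root", 1)
  out <- if (length(issues) == 0) {
    tibble::tibble(node_path = character(), problem = character())
  } else {
    dplyr::bind_rows(issues)
  }
  attr(out, "valid") <- nrow(out) == 0
  out
}

stop_if_invalid <- function(strat) {
  report <- validate_tree(strat)
  if (!attr(report, "valid")) {
    stop(
      "invalid decision tree for strategy '", strat$label, "':\n",
      paste0("  ", report$node_path, ": ", report$problem, collapse = "\n"),
      call. = FALSE
    )
  }
  invisible(strat)
}

#' Enumerate root-to-leaf pathways
#'
#' One row per terminal node: the joint probability (product of branch
#' probabilities along the pathway) and the terminal payoffs. Joint
#' probabilities sum to one for any valid tree.
#'
#' @param strat An `fp_strategy` (validated before enumeration).
#' @return Tibble with columns `path`, `prob`, `cost`, `effect`.
#' @export
enumerate_paths <- function(strat) {
  stop_if_invalid(strat)
  rows <- list()
  descend <- function(node, path, prob) {
    if (node$type == "terminal") {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        path = path, prob = prob, cost = node$cost, effect = node$effect
      )
    } else {
      for (i in seq_along(node$branches)) {
        b <- node$branches[[i]]
        descend(b$node, paste0(path, "/", i), prob * b$p)
      }
    }
  }
  descend(strat$root, "root", 1)
  dplyr::bind_rows(rows)
}

#' Roll back expected cost and effect
#'
#' Bottom-up expectation over the tree: at each chance node the
#' probability-weighted average of its children's (cost, effect), plus the
#' strategy's upfront per-entrant cost. Identical (at full precision) to
#' the dot product of joint path probabilities with terminal payoffs.
#'
#' @param strat An `fp_strategy`.
#' @return One-row tibble: `label`, `expected_cost`, `expected_effect`.
#' @export
rollback <- function(strat) {
  stop_if_invalid(strat)
  expect <- function(node) {
    if (node$type == "terminal") {
      return(c(cost = node$cost, effect = node$effect))
    }
    vals <- vapply(node$branches, function(b) b$p * expect(b$node), numeric(2))
    c(cost = sum(vals["cost", ]), effect = sum(vals["effect", ]))
  }
  e <- expect(strat$root)
  tibble::tibble(
    label = strat$label,
    expected_cost = strat$upfront_cost + unname(e["cost"]),
    expected_effect = unname(e["effect"])
  )
}

as_strategy_result <- function(x, fallback_label) {
  if (inherits(x, "fp_strategy")) {
    return(rollback(x))
  }
  if (is.data.frame(x) &&
    all(c("expected_cost", "expected_effect") %in% names(x)) && nrow(x) == 1) {
    if (!"label" %in% names(x)) x$label <- fallback_label
    return(tibble::as_tibble(x)[c("label", "expected_cost", "expected_effect")])
  }
  stop("strategies must be fp_strategy objects or one-row tibbles with ",
    "expected_cost and expected_effect",
    call. = FALSE
  )
}

#' Incremental cost-effectiveness comparison
#'
#' Compares an intervention strategy against a comparator on the same
#' effect scale. Incrementals are intervention minus comparator. The
#' dominance class is:
#' \describe{
#'   \item{dominant}{costs less and gains more effect (no ICER reported)}
#'   \item{dominated}{costs more and gains less}
#'   \item{equivalent}{both incrementals zero within `tol`}
#'   \item{tradeoff_icer}{otherwise; the ICER \eqn{\Delta C / \Delta E} is
#'     reported, or flagged undefined when \eqn{\Delta E = 0}}
#' }
#' The net monetary benefit is `wtp * delta_effect - delta_cost`.
#'
#' @param intervention,comparator `fp_strategy` objects or one-row tibbles
#'   with `expected_cost` / `expected_effect` (e.g. published
#'   probability-weighted values).
#' @param wtp Willingness to pay per unit effect, GBP (used for NMB only).
#' @param tol Tie tolerance on both incrementals (default 1e-9).
#' @return Object of class `fp_cea`; see [tidy.fp_cea()], [glance.fp_cea()],
#'   [autoplot.fp_cea()].
#' @examples
#' cea <- compare_strategies(
#'   tibble::tibble(label = "with Frame", expected_cost = 1095.38,
#'                  expected_effect = 1.261),
#'   tibble::tibble(label = "without Frame", expected_cost = 1563.07,
#'                  expected_effect = 1.125)
#' )
#' cea$dominance # "dominant"
#' @export
compare_strategies <- function(intervention, comparator, wtp = 20000,
                               tol = 1e-9) {
  a <- as_strategy_result(intervention, "intervention")
  b <- as_strategy_result(comparator, "comparator")
  dc <- a$expected_cost - b$expected_cost
  de <- a$expected_effect - b$expected_effect
  dominance <- if (abs(dc) <= tol && abs(de) <= tol) {
    "equivalent"
  } else if (dc < 0 && de > 0) {
    "dominant"
  } else if (dc > 0 && de < 0) {
    "dominated"
  } else {
    "tradeoff_icer"
  }
  icer <- if (dominance == "tradeoff_icer" && abs(de) > tol) dc / de else NA_real_
  structure(
    list(
      strategies = dplyr::bind_rows(a, b),
      delta_cost = dc,
      delta_effect = de,
      dominance = dominance,
      icer = icer,
      icer_defined = !is.na(icer),
      nmb = wtp * de - dc,
      wtp = wtp
    ),
    class = "fp_cea"
  )
}

#' @export
print.fp_cea <- function(x, ...) {
  cat("Cost-effectiveness comparison (", x$strategies$label[1], " vs ",
    x$strategies$label[2], ")\n",
    sep = ""
  )
  print(x$strategies)
  cat(sprintf(
    "incremental cost %.2f GBP, incremental effect %+.3f\n",
    x$delta_cost, x$delta_effect
  ))
  cat("dominance class:", x$dominance, "\n")
  if (x$icer_defined) cat(sprintf("ICER: %.2f GBP per unit effect\n", x$icer))
  cat(sprintf("NMB at WTP %.0f: %.2f GBP\n", x$wtp, x$nmb))
  invisible(x)
}

#' Tidy a cost-effectiveness comparison
#'
#' @param x An `fp_cea` object.
#' @param ... Unused.
#' @return Per-strategy tibble with incrementals attached to the
#'   intervention row.
#' @exportS3Method generics::tidy
tidy.fp_cea <- function(x, ...) {
  dplyr::mutate(x$strategies,
    role = c("intervention", "comparator"),
    delta_cost = c(x$delta_cost, NA_real_),
    delta_effect = c(x$delta_effect, NA_real_)
  )
}

#' Glance at a cost-effectiveness comparison
#'
#' @param x An `fp_cea` object.
#' @param ... Unused.
#' @return One-row tibble: incrementals, dominance class, ICER, NMB, WTP.
#' @exportS3Method generics::glance
glance.fp_cea <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    dominance = x$dominance,
    icer = x$icer,
    nmb = x$nmb,
    wtp = x$wtp
  )
}

#' Break-even device price
#'
#' The device price at which the intervention arm's incremental cost
#' reaches zero. Expected cost is affine in the device price with slope
#' `device_probability` (the probability an entrant incurs the device), so
#' the break-even point is
#' `current_price - incremental_cost / device_probability`.
#'
#' @param current_price Device price used in the comparison, GBP.
#' @param incremental_cost Incremental cost (intervention minus comparator)
#'   at `current_price`; negative when the intervention saves money.
#' @param device_probability Probability that an entrant incurs the device
#'   cost, in \eqn{(0, 1]}. 1 for a single-use device applied to all
#'   entrants.
#' @return Break-even price, GBP (unrounded; 963.52 for the base case).
#' @examples
#' break_even_price(495.83, -467.69) # 963.52
#' @export
break_even_price <- function(current_price, incremental_cost,
                             device_probability = 1) {
  check_scalar_nonneg(current_price, "current_price")
  stopifnot(is.numeric(incremental_cost), length(incremental_cost) == 1)
  if (!is.numeric(device_probability) || length(device_probability) != 1 ||
    device_probability <= 0 || device_probability > 1) {
    stop("no break-even price exists: device_probability must lie in (0, 1]",
      call. = FALSE
    )
  }
  current_price - incremental_cost / device_probability
}

#' Scale a per-patient value to a cohort
#'
#' @param per_patient_value GBP per patient.
#' @param n_patients Cohort size (>= 0).
#' @return `per_patient_value * n_patients`.
#' @examples
#' cohort_scale(467.69, 1120) # 523,812.8 -> "£0.52 million"
#' @export
cohort_scale <- function(per_patient_value, n_patients) {
  stopifnot(is.numeric(per_patient_value), length(per_patient_value) == 1)
  check_scalar_nonneg(n_patients, "n_patients")
  per_patient_value * n_patients
}

#' Monetary value of a cohort's health gain
#'
#' Values an HB-grade improvement using a per-grade-recovery valuation
#' (e.g. a Delphi panel's modal monetary rating) scaled over a cohort.
#'
#' @param hb_gain_per_patient HB-grade improvement per patient.
#' @param gbp_per_grade_recovery GBP valuation of one grade recovery.
#' @param n_patients Cohort size.
#' @return `hb_gain * value * n` in GBP.
#' @examples
#' value_health_gain(0.14, 19400, 6570) # ~17.8 million
#' @export
value_health_gain <- function(hb_gain_per_patient, gbp_per_grade_recovery,
                              n_patients) {
  check_scalar_nonneg(hb_gain_per_patient, "hb_gain_per_patient")
  check_scalar_nonneg(gbp_per_grade_recovery, "gbp_per_grade_recovery")
  check_scalar_nonneg(n_patients, "n_patients")
  hb_gain_per_patient * gbp_per_grade_recovery * n_patients
}

#' Cost of a full therapy course from an activity schedule
#'
#' A pathway cost schedule is a tibble with columns `activity`,
#' `unit_cost`, `units` and optionally `line_total`. Where a `line_total`
#' is supplied (e.g. a printed table subtotal) it is treated as
#' authoritative for that line; otherwise the line value is
#' `unit_cost * units`.
#'
#' @param schedule Pathway cost schedule tibble.
#' @return Total GBP for the full course.
#' @seealso [pathway_table()] for per-line computed-vs-stated flags.
#' @export
pathway_cost <- function(schedule) {
  sum(pathway_table(schedule)$line_value)
}

#' Per-line pathway costs with discrepancy flags
#'
#' @inheritParams pathway_cost
#' @return The schedule with `computed_total` (`unit_cost * units`),
#'   `line_value` (stated `line_total` where present, else computed) and
#'   `discrepant` (stated differs from computed by more than 1e-6 GBP).
#' @export
pathway_table <- function(schedule) {
  stopifnot(all(c("activity", "unit_cost", "units") %in% names(schedule)))
  if (any(schedule$units < 0) || any(schedule$unit_cost < 0)) {
    stop("unit_cost and units must be non-negative", call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(schedule),
    computed_total = .data$unit_cost * .data$units
  )
  if (!"line_total" %in% names(out)) out$line_total <- NA_real_
  dplyr::mutate(out,
    line_value = dplyr::coalesce(.data$line_total, .data$computed_total),
    discrepant = !is.na(.data$line_total) &
      abs(.data$line_total - .data$computed_total) > 1e-6
  )
}
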