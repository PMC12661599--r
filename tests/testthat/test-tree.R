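two_branch <- function(p1, p2) {
  strategy("s", chance_node(
    branch(p1, terminal_node(10, 1)),
    branch(p2, terminal_node(20, 0))
  ))
}

test_that("tree validation catches normalisation and payoff violations", {
  expect_true(attr(validate_tree(two_branch(0.6, 0.4)), "valid"))
  bad <- validate_tree(two_branch(0.6, 0.5))
  expect_false(attr(bad, "valid"))
  expect_match(bad$problem, "sum to", all = FALSE)
  neg <- strategy("s", chance_node(
    branch(1, structure(list(type = "terminal", cost = -5, effect = 1),
      class = "fp_node"
    ))
  ))
  expect_match(validate_tree(neg)$problem, "negative", all = FALSE)
  expect_false(attr(validate_tree(
    strategy("s", chance_node(branch(1, list(type = "bogus"))))
  ), "valid"))
})

test_that("path enumeration follows the product rule and sums to one", {
  single <- strategy("s", terminal_node(100, 2))
  paths <- enumerate_paths(single)
  expect_equal(nrow(paths), 1)
  expect_equal(paths$prob, 1)

  nested <- strategy("s", chance_node(
    branch(0.3, chance_node(
      branch(0.5, terminal_node(1, 1)),
      branch(0.5, terminal_node(2, 0))
    )),
    branch(0.7, terminal_node(3, 0.5))
  ))
  paths <- enumerate_paths(nested)
  expect_equal(sort(paths$prob), c(0.15, 0.15, 0.7))
  expect_equal(sum(paths$prob), 1)
  expect_error(enumerate_paths(two_branch(0.6, 0.5)), "invalid decision tree")
})

test_that("rollback matches the brute-force path-enumeration oracle", {
  set.seed(17)
  for (i in 1:120) {
    strat <- random_tree()
    expected <- oracle_expectation(strat)
    rolled <- rollback(strat)
    expect_equal(rolled$expected_cost, unname(expected["cost"]), tolerance = 1e-12)
    expect_equal(rolled$expected_effect, unname(expected["effect"]), tolerance = 1e-12)
    paths <- enumerate_paths(strat)
    expect_equal(sum(paths$prob), 1, tolerance = 1e-9)
    expect_equal(
      rolled$expected_cost, strat$upfront_cost + sum(paths$prob * paths$cost),
      tolerance = 1e-12
    )
  }
})

test_that("upfront cost shifts expected cost additively", {
  set.seed(23)
  strat <- random_tree()
  base <- rollback(strat)
  strat$upfront_cost <- strat$upfront_cost + 495.83
  shifted <- rollback(strat)
  expect_equal(shifted$expected_cost, base$expected_cost + 495.83)
  expect_equal(shifted$expected_effect, base$expected_effect)
})

test_that("dominance classification follows the incremental signs", {
  res <- function(cost, effect) {
    tibble::tibble(expected_cost = cost, expected_effect = effect)
  }
  expect_equal(compare_strategies(res(100, 2), res(200, 1))$dominance, "dominant")
  expect_equal(compare_strategies(res(200, 1), res(100, 2))$dominance, "dominated")
  eq <- compare_strategies(res(100, 1), res(100, 1))
  expect_equal(eq$dominance, "equivalent")
  expect_false(eq$icer_defined)

  tr <- compare_strategies(res(200, 1.5), res(100, 1))
  expect_equal(tr$dominance, "tradeoff_icer")
  expect_equal(tr$icer, 200)
  expect_equal(tr$nmb, 20000 * 0.5 - 100)

  undef <- compare_strategies(res(200, 1), res(100, 1))
  expect_equal(undef$dominance, "tradeoff_icer")
  expect_false(undef$icer_defined)
  expect_true(is.na(undef$icer))
})

test_that("dominance is invariant to positive rescaling of the effect axis", {
  set.seed(31)
  for (k in c(0.5, 2, 10)) {
    a <- tibble::tibble(expected_cost = 100, expected_effect = 2)
    b <- tibble::tibble(expected_cost = 200, expected_effect = 1)
    base <- compare_strategies(a, b)$dominance
    scaled <- compare_strategies(
      dplyr::mutate(a, expected_effect = expected_effect * k),
      dplyr::mutate(b, expected_effect = expected_effect * k)
    )$dominance
    expect_equal(scaled, base)
  }
})

test_that("published expected values classify the telerehabilitation arm dominant", {
  fx <- study_fixtures()
  cea <- compare_strategies(fx$cea$with_frame, fx$cea$without_frame)
  expect_equal(cea$dominance, "dominant")
  expect_equal(cea$delta_cost, -467.69, tolerance = 1e-9)
  expect_equal(cea$delta_effect, 0.136, tolerance = 1e-9)
  expect_equal(round_half_up(cea$delta_effect, 2), 0.14)
  td <- tidy(cea)
  expect_equal(td$role, c("intervention", "comparator"))
  expect_equal(glance(cea)$dominance, "dominant")
})

test_that("break-even price zeroes the incremental cost on a real tree", {
  expect_equal(break_even_price(495.83, -467.69, 1), 963.52)
  expect_equal(round_half_up(break_even_price(495.83, -467.69, 1)), 964)
  expect_equal(break_even_price(200, 0, 1), 200)
  expect_equal(break_even_price(495.83, -467.69, 0.5), 495.83 + 935.38)
  expect_error(break_even_price(100, -50, 0), "device_probability")

  # re-rollback oracle: set the device price to the break-even value and
  # confirm the incremental cost vanishes
  set.seed(41)
  for (i in 1:20) {
    arms <- gen_tree(seed = i, recovery_uplift = 0.15, device_cost = 495.83)
    cea <- compare_strategies(arms$intervention, arms$comparator)
    be <- break_even_price(arms$intervention$upfront_cost, cea$delta_cost, 1)
    arms$intervention$upfront_cost <- be
    cea2 <- compare_strategies(arms$intervention, arms$comparator)
    expect_lt(abs(cea2$delta_cost), 1e-6)
  }

  # device incurred with probability 0.5: device cost sits on one branch
  base_line <- terminal_node(1000, 1)
  make <- function(price) {
    strategy("half", chance_node(
      branch(0.5, terminal_node(1000 + price, 1)),
      branch(0.5, base_line)
    ))
  }
  comparator <- strategy("none", terminal_node(1200, 1))
  cea <- compare_strategies(make(495.83), comparator)
  be <- break_even_price(495.83, cea$delta_cost, 0.5)
  cea_at_be <- compare_strategies(make(be), comparator)
  expect_lt(abs(cea_at_be$delta_cost), 1e-6)
})

test_that("cohort scaling and health-gain valuation are exact products", {
  expect_equal(cohort_scale(467.69, 1120), 523812.8)
  expect_equal(gbp_millions(cohort_scale(467.69, 1120)), 0.52)
  expect_equal(cohort_scale(467.69, 6570), 3072723.3)
  expect_equal(cohort_scale(10, 0), 0)
  expect_equal(value_health_gain(0.14, 19400, 6570), 17844120)
  expect_equal(gbp_millions(value_health_gain(0.14, 19400, 6570), 1), 17.8)
  expect_equal(value_health_gain(0, 19400, 6570), 0)
  set.seed(19)
  for (i in 1:20) {
    v <- stats::runif(3, 0, 1e4)
    expect_equal(value_health_gain(v[1], v[2], v[3]), prod(v))
  }
})

test_that("pathway costs honour printed line totals and flag discrepancies", {
  fx <- study_fixtures()
  tab <- pathway_table(fx$fnmr_schedule)
  # botulinum line: printed 2475.65 stands in for 10 x 247.57 = 2475.70
  bot <- tab[grepl("Botulinum", tab$activity), ]
  expect_equal(bot$line_value, 2475.65)
  expect_equal(bot$computed_total, 2475.70)
  expect_true(bot$discrepant)
  expect_equal(pathway_cost(fx$fnmr_schedule), 3126.15, tolerance = 1e-9)
  expect_equal(
    pathway_cost(tibble::tibble(
      activity = character(), unit_cost = numeric(), units = numeric()
    )), 0
  )
  # without stated totals the computed products are used
  plain <- tibble::tibble(activity = c("a", "b"), unit_cost = c(10, 5), units = c(2, 3))
  expect_equal(pathway_cost(plain), 35)
})

test_that("strategies round-trip through the JSON tree document format", {
  set.seed(53)
  arms <- gen_tree(seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_strategies(arms, path)
  back <- read_strategies(path)
  expect_named(back, c("intervention", "comparator"))
  for (nm in names(back)) {
    expect_equal(rollback(back[[nm]]), rollback(arms[[nm]]), tolerance = 1e-12)
  }
  # malformed documents are rejected on load
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"s": {"upfront_cost": 0, "root": {"type": "chance",
    "branches": [{"p": 0.6, "node": {"type": "terminal", "cost": 1, "effect": 1}},
                 {"p": 0.5, "node": {"type": "terminal", "cost": 1, "effect": 1}}]}}}', bad)
  expect_error(read_strategies(bad), "invalid decision tree")
})
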