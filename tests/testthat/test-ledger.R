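test_that("line-item costs are volume times unit cost", {
  led <- cost_ledger(
    activity = c("GP consultations", "elective inpatient", "zero volume"),
    volume = c(67971, 22457, 0),
    unit_cost = c(39.00, 3573, 39.00),
    category = c("medical/primary-care", "medical/inpatient", "medical/primary-care")
  )
  costed <- line_item_cost(led)
  expect_equal(costed$total_cost, c(2650869, 80238861, 0), tolerance = 1e-9)
})

test_that("invalid line items are rejected", {
  expect_error(
    cost_ledger("x", volume = -1, unit_cost = 10, category = "a"),
    "non-negative"
  )
  expect_error(
    cost_ledger("x", volume = 1, unit_cost = -10, category = "a"),
    "non-negative"
  )
  expect_error(
    cost_ledger("x", volume = 1, unit_cost = 10, category = ""),
    "non-empty"
  )
})

test_that("inflation re-indexing follows the index ratio and round-trips", {
  idx <- c("2019/2020" = 1.00, "2020/2021" = 1.05)
  expect_equal(inflate_cost(100, "2020/2021", "2020/2021", idx), 100)
  expect_equal(inflate_cost(100, "2019/2020", "2020/2021", idx), 105)
  expect_error(inflate_cost(100, "1999/2000", "2020/2021", idx), "not present")
  expect_error(
    inflate_cost(100, "2019/2020", "2020/2021", c("2019/2020" = 0, "2020/2021" = 1)),
    "positive"
  )
  # seeded random two-point indexes: ratio oracle and inverse round-trip
  set.seed(11)
  for (i in 1:25) {
    idx <- stats::setNames(stats::runif(2, 0.5, 2), c("a", "b"))
    cost <- stats::runif(1, 1, 1e6)
    expect_equal(inflate_cost(cost, "a", "b", idx), cost * idx["b"] / idx["a"],
      ignore_attr = TRUE
    )
    expect_equal(
      inflate_cost(inflate_cost(cost, "a", "b", idx), "b", "a", idx),
      cost,
      tolerance = 1e-9
    )
  }
})

test_that("published treatment ledger reproduces table subtotals and shares", {
  led <- study_fixtures()$treatment_ledger
  expect_equal(subtotal(led, "medical/primary-care"), 3765193.05, tolerance = 1e-8)
  expect_equal(subtotal(led, "medical/outpatient"), 2334922)
  expect_equal(subtotal(led, "medical/inpatient"), 80238861)
  expect_equal(round_half_up(subtotal(led, "therapy")), 643292)
  expect_equal(gbp_millions(subtotal(led, "medical"), 3), 86.339)
  expect_equal(gbp_millions(grand_total(led)), 86.98)
  expect_equal(subtotal(cost_ledger(character(), numeric(), numeric(), character()), "x"), 0)

  expect_equal(
    round_half_up(category_share(led, "medical/inpatient", "medical"), 1), 92.9
  )
  expect_equal(
    round_half_up(category_share(led, "medical/outpatient", "medical"), 1), 2.7
  )
  expect_equal(
    round_half_up(category_share(led, "medical/primary-care", "medical"), 1), 4.4
  )
  expect_equal(
    round_half_up(category_share(led, "therapy/fnmr", "therapy"), 1), 31.3
  )
  expect_equal(category_share(led, "medical", "medical"), 100)
  expect_error(category_share(led, "medical", "nonexistent"), "positive")
})

test_that("grand total equals any exhaustive disjoint partition of subtotals", {
  set.seed(42)
  for (i in 1:20) {
    led <- gen_ledger(n_items = sample(1:30, 1), seed = i)
    # brute-force item sum oracle
    expect_equal(grand_total(led), sum(led$volume * led$unit_cost))
    tops <- unique(sub("/.*$", "", led$category))
    expect_equal(
      grand_total(led),
      sum(vapply(tops, function(tp) subtotal(led, tp), numeric(1)))
    )
    shares <- vapply(tops, function(tp) category_share(led, tp), numeric(1))
    expect_equal(sum(shares), 100, tolerance = 1e-9)
  }
})

test_that("line-item cost is homogeneous in volume", {
  led <- gen_ledger(n_items = 8, seed = 5)
  doubled <- dplyr::mutate(led, volume = volume * 2)
  expect_equal(grand_total(doubled), 2 * grand_total(led))
})

test_that("ledger CSV IO round-trips", {
  led <- gen_ledger(n_items = 12, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, path)
  back <- read_ledger(path)
  expect_equal(as.data.frame(back), as.data.frame(led))
})
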