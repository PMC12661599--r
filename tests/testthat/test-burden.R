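test_that("remaining lifetime is life expectancy minus age at diagnosis", {
  expect_equal(lifetime_duration(37.5, 81.6), 44.1)
  expect_equal(lifetime_duration(30, 40), 10)
  expect_error(lifetime_duration(81.6, 37.5), "exceed")
  set.seed(3)
  for (i in 1:20) {
    ages <- sort(stats::runif(2, 0, 100))
    expect_equal(lifetime_duration(ages[1], ages[2]), ages[2] - ages[1])
  }
})

test_that("QALY losses reproduce the published per-state rows", {
  cohort <- study_fixtures()$cohort
  out <- qaly_loss(cohort, 0.04)
  expect_equal(out$qalys_lost, c(321.72, 5194.98, 6394.5), tolerance = 1e-9)
  # 6394.5 must round *up* to the printed 6395 (half-up, not half-even)
  expect_equal(out$qalys_lost_rounded, c(322, 5195, 6395))
  expect_equal(sum(out$qalys_lost_rounded), 11912)
  expect_equal(qaly_loss(cohort, 0)$qalys_lost, c(0, 0, 0))
  expect_error(qaly_loss(cohort, 1.5), "\\[0, 1\\]")
})

test_that("qaly_loss is linear in cases, duration, and decrement", {
  base <- recovery_cohort("partial", 1000, 10)
  q0 <- qaly_loss(base, 0.04)$qalys_lost
  expect_equal(qaly_loss(recovery_cohort("partial", 2000, 10), 0.04)$qalys_lost, 2 * q0)
  expect_equal(qaly_loss(recovery_cohort("partial", 1000, 20), 0.04)$qalys_lost, 2 * q0)
  expect_equal(qaly_loss(base, 0.08)$qalys_lost, 2 * q0)
})

test_that("decrement calibration inverts the QALY-loss relationship", {
  expect_equal(calibrate_decrement(5195, 2945, 44.1), 0.04, tolerance = 1e-4)
  expect_equal(calibrate_decrement(0, 100, 10), 0)
  expect_error(calibrate_decrement(100, 0, 10), "positive")
  set.seed(8)
  for (i in 1:25) {
    cases <- stats::runif(1, 1, 1e5)
    dur <- stats::runif(1, 0.1, 60)
    dec <- stats::runif(1, 0, 1)
    q <- qaly_loss(recovery_cohort("partial", cases, dur), dec)$qalys_lost
    expect_equal(calibrate_decrement(q, cases, dur), dec, tolerance = 1e-12)
  }
})

test_that("monetisation and societal costs scale interval bounds", {
  m <- monetize_qalys(11912, 20000, 30000)
  expect_equal(m$low, 238240000)
  expect_equal(m$high, 357360000)
  expect_equal(monetize_qalys(0), money_interval(0, 0))
  m2 <- monetize_qalys(5195, 20000, 30000)
  expect_equal(gbp_millions(m2$low, 1), 103.9)
  expect_equal(gbp_millions(m2$high, 2), 155.85)

  s <- societal_cost(22657, 5000, 10000)
  expect_equal(s$low, 113285000)
  expect_equal(s$high, 226570000)
  expect_equal(gbp_millions(s$low, 1), 113.3)
  expect_equal(gbp_millions(s$high, 1), 226.6)
  expect_equal(societal_cost(0), money_interval(0, 0))
})

test_that("interval operations preserve ordering and add component-wise", {
  expect_error(money_interval(10, 5), "low <= high")
  set.seed(13)
  for (i in 1:25) {
    a <- sort(stats::runif(2, 0, 1e8))
    b <- sort(stats::runif(2, 0, 1e8))
    total <- total_burden(money_interval(a[1], a[2]), money_interval(b[1], b[2]))
    expect_equal(total$low, a[1] + b[1])
    expect_equal(total$high, a[2] + b[2])
    expect_lte(total$low, total$high)
  }
  x <- money_interval(5, 7)
  expect_equal(total_burden(money_interval(0, 0), x), x)
})

test_that("total burden of the annual cohort reaches the published band", {
  fx <- study_fixtures()
  bt <- burden_table(fx$cohort, 0.04)
  total <- bt[bt$state == "total", ]
  expect_equal(total$qalys_lost_rounded, 11912)
  burden <- total_burden(
    monetize_qalys(total$qalys_lost_rounded),
    societal_cost(fx$burden_params$total_cases)
  )
  expect_equal(gbp_millions(burden$high, 0), 584)
  # the unrounded low bound is 351.5m; printed "£351 million" truncates
  expect_equal(round(burden$low / 1e6, 1), 351.5)
})

test_that("discount-rate hook reduces effective years and defaults to none", {
  cohort <- recovery_cohort("partial", 1000, 40)
  undiscounted <- qaly_loss(cohort, 0.04)$qalys_lost
  discounted <- qaly_loss(cohort, 0.04, discount_rate = 0.035)$qalys_lost
  expect_lt(discounted, undiscounted)
  expect_equal(undiscounted, 1000 * 40 * 0.04)
})
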