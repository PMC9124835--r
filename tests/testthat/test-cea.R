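test_that("an inert screening test changes costs but not health", {
  th <- crc_params(); tk <- crc_fixed_params(); lt <- make_life_table()
  cea0 <- cea_params(sens_small = 0, sens_large_crc = 0)
  rs <- simulate_strategy(th, tk, lt, cea0, "colonoscopy_q10",
                          n = 3000, seed = 8)
  rn <- simulate_strategy(th, tk, lt, cea0, "no_screening",
                          n = 3000, seed = 8)
  # common random numbers + zero sensitivity: identical disease histories
  expect_equal(rs$qaly_i, rn$qaly_i)
  inc <- incremental_outcomes(rs, rn)
  expect_equal(inc$delta_qaly, 0)
  expect_gt(inc$delta_cost, 0)
  # the cost difference is exactly the discounted colonoscopy spend
  cea00 <- cea_params(sens_small = 0, sens_large_crc = 0,
                      cost_early_annual = 0, cost_late_annual = 0)
  rs0 <- simulate_strategy(th, tk, lt, cea00, "colonoscopy_q10",
                           n = 2000, seed = 9)
  rn0 <- simulate_strategy(th, tk, lt, cea00, "no_screening",
                           n = 2000, seed = 9)
  expect_equal(rn0$cost, 0)
  expect_gt(rs0$cost, 0)
})

test_that("without screening, unit utilities return discounted survival", {
  tk0 <- crc_fixed_params(p_preclin_early_50 = 0, p_preclin_late_50 = 0)
  lt <- make_life_table()
  cea1 <- cea_params(discount_rate = 0, cost_early_annual = 0,
                     cost_late_annual = 0)
  r <- simulate_strategy(inert_params(), tk0, lt, cea1, "no_screening",
                         n = 20000, seed = 10)
  expect_equal(r$cost, 0)
  # undiscounted QALYs at unit utility = expected years lived (end-of-cycle
  # counting), close to the life-table expectation at 50
  expect_lt(abs(r$qaly - life_expectancy(lt, 50)), 1)
})

test_that("incremental outcomes difference the strategy means", {
  mk <- function(cost, qaly, n = 5)
    structure(list(cost = cost, qaly = qaly, n = n),
              class = "crc_strategy_result")
  inc <- incremental_outcomes(mk(100, 2), mk(50, 1.5))
  expect_equal(inc$delta_cost, 50)
  expect_equal(inc$delta_qaly, 0.5)
  inc0 <- incremental_outcomes(mk(70, 1), mk(70, 1))
  expect_equal(inc0$delta_cost, 0)
  expect_equal(inc0$delta_qaly, 0)
  expect_error(incremental_outcomes(mk(1, 1, n = 5), mk(1, 1, n = 6)),
               "different cohort sizes")
})

test_that("screening shifts stage and buys QALYs at the generating truth", {
  th <- crc_params(); tk <- crc_fixed_params(); lt <- make_life_table()
  rs <- simulate_strategy(th, tk, lt, cea_params(), "colonoscopy_q10",
                          n = 10000, seed = 12)
  rn <- simulate_strategy(th, tk, lt, cea_params(), "no_screening",
                          n = 10000, seed = 12)
  inc <- incremental_outcomes(rs, rn)
  expect_gt(inc$delta_qaly, 0)
  expect_gt(inc$delta_cost, 0)
  expect_lt(rs$n_clin_late, rn$n_clin_late)
})

test_that("raising the colonoscopy price moves only costs", {
  th <- crc_params(); tk <- crc_fixed_params(); lt <- make_life_table()
  run <- function(price) {
    rs <- simulate_strategy(th, tk, lt,
                            cea_params(cost_colonoscopy = price),
                            "colonoscopy_q10", n = 3000, seed = 14)
    rn <- simulate_strategy(th, tk, lt,
                            cea_params(cost_colonoscopy = price),
                            "no_screening", n = 3000, seed = 14)
    incremental_outcomes(rs, rn)
  }
  a <- run(10000); b <- run(15000)
  expect_gt(b$delta_cost, a$delta_cost)
  expect_equal(a$delta_qaly, b$delta_qaly)
})

test_that("perfect sensitivity weakly reduces late-stage disease", {
  th <- crc_params(); tk <- crc_fixed_params(); lt <- make_life_table()
  cea1 <- cea_params(sens_small = 1, sens_large_crc = 1)
  rs <- simulate_strategy(th, tk, lt, cea1, "colonoscopy_q10",
                          n = 10000, seed = 15)
  rn <- simulate_strategy(th, tk, lt, cea1, "no_screening",
                          n = 10000, seed = 15)
  expect_lte(rs$n_clin_late, rn$n_clin_late)
})

test_that("common random numbers reduce incremental variance", {
  th <- crc_params(); tk <- crc_fixed_params(); lt <- make_life_table()
  rs <- simulate_strategy(th, tk, lt, cea_params(), "colonoscopy_q10",
                          n = 5000, seed = 16)
  rn <- simulate_strategy(th, tk, lt, cea_params(), "no_screening",
                          n = 5000, seed = 16)
  paired <- var(rs$qaly_i - rn$qaly_i)
  unpaired <- var(rs$qaly_i) + var(rn$qaly_i)
  expect_lt(paired, unpaired)
})
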