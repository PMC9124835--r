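test_that("adenoma onset hazard follows the Weibull form", {
  # direct high-precision evaluation of l * gamma * a^(gamma - 1)
  expect_equal(weibull_hazard(50, 2.86e-06, 2.78),
               2.86e-06 * 2.78 * exp(1.78 * log(50)))
  expect_equal(weibull_hazard(50, 2.86e-06, 2.78), 8.41e-03,
               tolerance = 1e-3)
  expect_equal(weibull_hazard(37, 0.02, 1), 0.02)  # shape 1: constant
  expect_equal(weibull_hazard(0, 1e-5, 2.78), 0)
  expect_true(all(diff(weibull_hazard(40:90, 2.86e-06, 2.78)) > 0))
  expect_error(weibull_hazard(-1, 1e-5, 2), "non-negative")
  expect_error(weibull_hazard(50, 0, 2), "positive")
  expect_error(weibull_hazard(50, 1e-5, -1), "positive")
})

test_that("intensity matrix has the model's transition structure", {
  th <- crc_params(); tk <- crc_fixed_params()
  Q <- build_intensity_matrix(th, tk, mu_a = 0, a = 50)
  expect_equal(Q["normal", "small_adenoma"],
               weibull_hazard(50, th[["l"]], th[["gamma"]]))
  expect_equal(Q["small_adenoma", "large_adenoma"], 0.0346)
  expect_equal(Q["preclin_early_crc", "preclin_late_crc"], 0.3697)
  expect_equal(Q["preclin_early_crc", "clin_early_crc"], 0.2382)
  expect_equal(Q["clin_late_crc", "crc_death"], 0.2099)
  # clinical early never progresses to clinical late in this model
  expect_equal(Q["clin_early_crc", "clin_late_crc"], 0)
  # absorbing death states
  expect_equal(Q["crc_death", ], setNames(numeric(9), crc_states))
  expect_equal(Q["other_death", ], setNames(numeric(9), crc_states))
  # (effectively) all-zero rates give the zero matrix
  th0 <- setNames(c(0.5, 0.5, 1e-300, 1, 0, 0, 0, 0, 0),
                  names(crc_params()))
  tk0 <- c(lambda7 = 0, lambda8 = 0,
           p_preclin_early_50 = 0, p_preclin_late_50 = 0)
  Q0 <- build_intensity_matrix(th0, tk0, mu_a = 0, a = 60)
  expect_equal(unname(Q0), matrix(0, 9, 9))
  # conservation and sign structure over random draws
  set.seed(42)
  for (i in 1:50) {
    Qr <- random_intensity()
    expect_lt(max(abs(rowSums(Qr))), 1e-12)
    off <- Qr; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("annual transition matrices are the matrix exponential of Q", {
  expect_equal(transition_probability_matrix(matrix(0, 9, 9)), diag(9))
  # 2-state closed form
  Q2 <- matrix(c(-0.0346, 0.0346, 0, 0), 2, 2, byrow = TRUE)
  P2 <- transition_probability_matrix(Q2)
  expect_equal(P2[1, 2], 1 - exp(-0.0346), tolerance = 1e-12)
  # multi-jump transitions in a single year are possible
  P <- transition_probability_matrix(
    build_intensity_matrix(crc_params(), crc_fixed_params(), 0.005, 60))
  expect_gt(P["small_adenoma", "preclin_early_crc"], 0)
  expect_gt(P["preclin_early_crc", "crc_death"], 0)
  # non-conservative input refused
  expect_error(transition_probability_matrix(matrix(1, 9, 9)),
               "sum to zero")
})

test_that("transition matrices agree with the series oracle and are stochastic", {
  set.seed(7)
  for (i in 1:100) {
    Q <- random_intensity()
    P <- transition_probability_matrix(Q)
    expect_lt(max(abs(P - series_expm(Q))), 1e-9)
  }
  set.seed(8)
  for (i in 1:1000) {
    P <- transition_probability_matrix(random_intensity())
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P[8, 8], 1)
    expect_equal(P[9, 9], 1)
  }
})

test_that("initial cohort distribution splits prevalence as specified", {
  v <- initial_state_distribution(crc_params(padeno = 0.25, psmall = 0.71),
                                  crc_fixed_params())
  expect_equal(unname(v[c("small_adenoma", "large_adenoma", "normal")]),
               c(0.1775, 0.0725, 0.748))
  expect_equal(unname(v["preclin_early_crc"]), 0.0012)
  expect_equal(sum(v), 1)
  expect_true(all(v[6:9] == 0))
  # no adenomas at baseline
  th0 <- setNames(c(0, 0.5, 1e-6, 2, .1, .1, .1, .1, .1),
                  names(crc_params()))
  v0 <- initial_state_distribution(th0, crc_fixed_params())
  expect_equal(unname(v0["normal"]), 1 - 0.002)
  # impossible prevalence refused
  expect_error(initial_state_distribution(
    setNames(c(0.999, 0.5, 1e-6, 2, .1, .1, .1, .1, .1),
             names(crc_params())),
    crc_fixed_params(p_preclin_early_50 = 0.0005, p_preclin_late_50 = 0)),
    NA)
  expect_error(initial_state_distribution(
    setNames(c(1.5, 0.5, 1e-6, 2, .1, .1, .1, .1, .1),
             names(crc_params())), crc_fixed_params()),
    "exceed")
})

test_that("cohort trace propagates occupancy and conserves probability", {
  th <- crc_params(); tk <- crc_fixed_params(); lt <- make_life_table()
  tr <- cohort_trace(th, tk, lt)
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 51), tolerance = 1e-10)
  expect_true(all(tr$occupancy >= 0))
  expect_true(all(tr$flows >= 0))
  # adenoma prevalence among the alive rises over ages 50-70
  prev <- rowSums(tr$occupancy[, 2:3]) / rowSums(tr$occupancy[, 1:7])
  expect_true(all(diff(prev[1:21]) > 0))
  # inert parameters, no mortality: occupancy is constant
  tr0 <- cohort_trace(inert_params(), crc_fixed_params(
    p_preclin_early_50 = 0, p_preclin_late_50 = 0), zero_mortality_lt())
  expect_equal(tr0$occupancy[51, ], tr0$occupancy[1, ], tolerance = 1e-9)
  # overwhelming other-cause mortality absorbs everyone
  trm <- cohort_trace(th, tk, make_life_table(A = 5, B = 0, k = 0))
  expect_gt(trm$occupancy[51, "other_death"], 0.999)
})

test_that("pure-onset trace matches the exponential closed form", {
  r <- 0.03
  th <- inert_params()
  th["l"] <- r; th["gamma"] <- 1  # constant onset hazard r
  tk <- crc_fixed_params(p_preclin_early_50 = 0, p_preclin_late_50 = 0)
  tr <- cohort_trace(th, tk, zero_mortality_lt())
  k <- 0:50
  expect_equal(unname(tr$occupancy[, "normal"]), exp(-r * k),
               tolerance = 1e-9)
})

test_that("faster adenoma-to-cancer progression raises cumulative incidence", {
  tk <- crc_fixed_params(); lt <- make_life_table()
  cum_inc <- function(l3) {
    tr <- cohort_trace(crc_params(lambda3 = l3), tk, lt)
    sum(tr$flows)
  }
  vals <- vapply(c(0.01, 0.0215, 0.05, 0.1), cum_inc, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("model outputs reduce the trace with registry conventions", {
  # hand-built single-age trace: small 0.1, large 0.05, everyone alive
  occ <- matrix(0, 2, 9, dimnames = list(55:56, crc_states))
  occ[, "normal"] <- 0.85; occ[, "small_adenoma"] <- 0.1
  occ[, "large_adenoma"] <- 0.05
  tr <- structure(list(occupancy = occ,
                       flows = matrix(0, 1, 2,
                                      dimnames = list(55, c("new_clin_early",
                                                            "new_clin_late"))),
                       at_risk = rowSums(occ[, 1:5]), ages = 55:56),
                  class = "crc_trace")
  out <- model_outputs(tr, crc_age_bins(prev_ages = 55, inc_lo = 55,
                                        inc_width = 1))
  expect_equal(out$value[out$target_type == "adenoma_prev"], 0.15)
  expect_equal(out$value[out$target_type == "prop_small"], 2 / 3)
  expect_equal(out$value[out$target_type == "inc_early"], 0)
  # zero adenoma occupancy: prevalence 0, proportion small undefined
  occ2 <- occ; occ2[, 2:3] <- 0; occ2[, 1] <- 1
  tr2 <- tr; tr2$occupancy <- occ2; tr2$at_risk <- rowSums(occ2[, 1:5])
  out2 <- model_outputs(tr2, crc_age_bins(prev_ages = 55, inc_lo = 55,
                                          inc_width = 1))
  expect_equal(out2$value[out2$target_type == "adenoma_prev"], 0)
  expect_true(is.na(out2$value[out2$target_type == "prop_small"]))
  expect_error(model_outputs(tr, crc_age_bins()), "outside")
})
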