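test_that("beta moment matching solves the moment equations", {
  expect_equal(unname(moment_match_beta(0.5, sqrt(1 / 12))),
               c(1, 1), tolerance = 1e-12)
  ab <- moment_match_beta(0.264, 0.008)
  # hand-evaluated: k = m(1-m)/sd^2 - 1
  k <- 0.264 * 0.736 / 0.008^2 - 1
  expect_equal(unname(ab), c(0.264 * k, 0.736 * k))
  expect_equal(unname(ab), c(801.2, 2233.8), tolerance = 1e-3)
  # round trip through the distribution's own moments
  expect_equal(ab[[1]] / sum(ab), 0.264)
  expect_error(moment_match_beta(0.5, 0.6), "too large")
  expect_error(moment_match_beta(0.5, 0), "positive")
})

test_that("lognormal moment matching solves the moment equations", {
  ms <- moment_match_lognormal(0.035, 0.002)
  expect_equal(unname(ms), c(-3.3540, 0.0571), tolerance = 1e-3)
  # sampling reproduces the requested moments
  set.seed(3)
  x <- rlnorm(1e6, ms[1], ms[2])
  expect_equal(mean(x), 0.035, tolerance = 0.005)
  expect_equal(sd(x), 0.002, tolerance = 0.01)
  # vanishing sd limit
  ms0 <- moment_match_lognormal(2, 1e-9)
  expect_equal(ms0[["meanlog"]], log(2), tolerance = 1e-9)
  expect_error(moment_match_lognormal(-1, 1))
  expect_error(moment_match_lognormal(1, 0), "positive")
})

test_that("external distributions reproduce printed values and ranges", {
  ext <- fit_external_distributions()
  ss <- ext[ext$name == "sens_small", ]
  expect_equal(qbeta(0.025, ss$par1, ss$par2), 0.734, tolerance = 0.002)
  expect_equal(qbeta(0.975, ss$par1, ss$par2), 0.808, tolerance = 0.002)
  expect_equal(ss$par1 / (ss$par1 + ss$par2), 0.773)  # mean anchored
  # lognormal rows: mean anchored, percentiles near the printed range
  cc <- ext[ext$name == "cost_colonoscopy", ]
  expect_equal(exp(cc$par1 + cc$par2^2 / 2), 10000, tolerance = 1e-6)
  expect_equal(qlnorm(0.025, cc$par1, cc$par2), 9000, tolerance = 0.02)
  # sampled means match printed values within 1%
  set.seed(5)
  d <- sample_external(ext, 200000)
  rel <- abs(colMeans(d) - ext$value) / ext$value
  expect_true(all(rel < 0.01))
  # utilities never exceed 1
  expect_lte(max(d[, "util_preclin"]), 1)
  # degenerate range = point mass
  tab <- cea_param_table()
  tab$lo[1] <- tab$hi[1] <- tab$value[1]
  extp <- fit_external_distributions(tab)
  expect_true(is.na(extp$par1[1]))
  expect_true(all(sample_external(extp, 10)[, 1] == tab$value[1]))
  # value outside range refused
  tab2 <- cea_param_table(); tab2$value[2] <- 0.5
  expect_error(fit_external_distributions(tab2), "outside")
})

test_that("the four uncertainty characterizations draw as defined", {
  fit <- acceptance_fit()
  ext <- fit_external_distributions()
  d2 <- draw_parameters("A2_map_plus_external", fit, ext, 200, seed = 1)
  expect_true(all(apply(d2$theta, 2, sd) == 0))
  expect_equal(unname(d2$theta[1, ]), unname(fit$map))
  expect_gt(sd(d2$external[, "sens_small"]), 0)
  d3 <- draw_parameters("A3_posterior_only", fit, ext, 200, seed = 1)
  expect_true(all(apply(d3$external, 2, sd) == 0))
  expect_gt(sd(d3$theta[, "padeno"]), 0)
  # A4: independent marginals matching posterior moments
  d4 <- draw_parameters("A4_moments_independent_plus_external", fit, ext,
                        4000, seed = 2)
  rs <- fit$posterior$resample
  expect_equal(colMeans(d4$theta), colMeans(rs), tolerance = 0.02)
  cm <- cor(d4$theta)
  expect_lt(abs(cm["l", "gamma"]), 0.08)       # posterior corr ~ -0.9
  expect_lt(abs(cm["lambda4", "lambda5"]), 0.08)
  d1 <- draw_parameters("A1_posterior_plus_external", fit, ext, 200,
                        seed = 1)
  expect_true(all(d1$theta %in% rs))
  expect_error(draw_parameters("A5", fit, ext, 10), "arg")
})

test_that("net benefit is linear accounting", {
  expect_equal(net_benefit(50000, 1, 66000), 16000)
  expect_equal(net_benefit(c(10, 20), c(0, 0), 0), c(-10, -20))
  w <- c(0, 1e4, 5e4)
  expect_equal(net_benefit(100, 2, w), 2 * w - 100)
  expect_error(net_benefit(1, 1, -5), "wtp")
})

test_that("EVPI equals brute-force enumeration on toy tables", {
  # two equiprobable draws, NB_screen = (10, 0), NB_none = (0, 4) at wtp 0
  toy <- data.frame(cost_screen = c(-10, 0), qaly_screen = 0,
                    cost_none = c(0, -4), qaly_none = 0)
  ev <- evpi_curve(toy, wtp_grid = c(0, 1000))
  expect_equal(ev$evpi, c(2, 2))  # E[max]=7, max(E)=5
  # exhaustive check on a random 5-draw table against direct enumeration
  set.seed(9)
  tab <- data.frame(cost_screen = runif(5, 0, 100),
                    qaly_screen = runif(5, 0, 2),
                    cost_none = runif(5, 0, 100),
                    qaly_none = runif(5, 0, 2))
  for (w in c(0, 40, 120)) {
    nb_s <- w * tab$qaly_screen - tab$cost_screen
    nb_n <- w * tab$qaly_none - tab$cost_none
    manual <- mean(pmax(nb_s, nb_n)) - max(mean(nb_s), mean(nb_n))
    expect_equal(evpi_curve(tab, w)$evpi, manual)
  }
  # one strategy dominant in every draw: no value of information
  dom <- data.frame(cost_screen = 1, qaly_screen = 2,
                    cost_none = 100, qaly_none = c(0.1, 0.2, 0.3))
  expect_equal(evpi_curve(dom, c(0, 50000))$evpi, c(0, 0))
  expect_error(evpi_curve(dom[0, ], 0), "empty")
  expect_error(evpi_curve(data.frame(a = 1), 0), "lacks")
})

test_that("PSA runs are reproducible and well-formed", {
  fit <- acceptance_fit()
  ext <- fit_external_distributions()
  p1 <- run_psa("A2_map_plus_external", fit, ext, n_psa = 4,
                n_micro = 400, seed = 7)
  p2 <- run_psa("A2_map_plus_external", fit, ext, n_psa = 4,
                n_micro = 400, seed = 7)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), 4)
  expect_true(all(is.finite(as.matrix(p1[, -1]))))
  expect_equal(p1$dcost, p1$cost_screen - p1$cost_none)
  expect_equal(attr(p1, "approach"), "A2_map_plus_external")
})
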