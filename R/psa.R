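#' Four characterizations of calibrated-parameter uncertainty
#'
#' The PSA can characterize the uncertainty of the calibrated
#' natural-history parameters in four ways:
#' \describe{
#'   \item{A1_posterior_plus_external}{calibrated parameters resampled from
#'     the joint IMIS posterior; external parameters sampled from their
#'     fitted distributions.}
#'   \item{A2_map_plus_external}{calibrated parameters fixed at the MAP
#'     estimate; external parameters sampled.}
#'   \item{A3_posterior_only}{calibrated parameters from the posterior;
#'     external parameters fixed at their mean values.}
#'   \item{A4_moments_independent_plus_external}{each calibrated parameter
#'     sampled independently from a distribution moment-matched to its
#'     posterior mean and SD (beta for the two proportions, lognormal for
#'     the positive parameters), ignoring posterior correlations; external
#'     parameters sampled.}
#' }
#'
#' @format Character vector of the four approach names.
#' @export
uq_approaches <- c("A1_posterior_plus_external", "A2_map_plus_external",
                   "A3_posterior_only",
                   "A4_moments_independent_plus_external")

#' Draw calibrated and external parameters for a PSA
#'
#' @param approach One of [uq_approaches].
#' @param calib A [crc_calibrate()] fit.
#' @param ext A [fit_external_distributions()] object.
#' @param n_psa Number of PSA draws.
#' @param seed Integer seed.
#' @return List with `theta` (n_psa x 9) and `external` (n_psa x k)
#'   matrices.
#' @export
draw_parameters <- function(approach, calib, ext, n_psa, seed = 1) {
  approach <- match.arg(approach, uq_approaches)
  stopifnot(inherits(calib, "crc_calib"))
  set.seed(seed)
  rs <- calib$posterior$resample
  theta <- switch(approach,
    A1_posterior_plus_external = ,
    A3_posterior_only =
      rs[sample.int(nrow(rs), n_psa, replace = TRUE), , drop = FALSE],
    A2_map_plus_external =
      matrix(calib$map, n_psa, 9, byrow = TRUE,
             dimnames = list(NULL, colnames(rs))),
    A4_moments_independent_plus_external = {
      mom <- cbind(mean = colMeans(rs), sd = apply(rs, 2, stats::sd))
      draws <- sapply(rownames(mom), function(p) {
        if (p %in% c("padeno", "psmall")) {
          ab <- moment_match_beta(mom[p, 1], mom[p, 2])
          stats::rbeta(n_psa, ab[1], ab[2])
        } else {
          ms <- moment_match_lognormal(mom[p, 1], mom[p, 2])
          stats::rlnorm(n_psa, ms[1], ms[2])
        }
      })
      matrix(draws, nrow = n_psa, dimnames = list(NULL, rownames(mom)))
    })
  external <- if (approach == "A3_posterior_only") {
    matrix(ext$value, n_psa, nrow(ext), byrow = TRUE,
           dimnames = list(NULL, ext$name))
  } else {
    sample_external(ext, n_psa)
  }
  list(theta = theta, external = external)
}

#' Probabilistic sensitivity analysis of screening vs no screening
#'
#' For each PSA draw, simulates both strategies with common random numbers
#' and records per-strategy discounted costs and QALYs and their
#' increments.
#'
#' @inheritParams draw_parameters
#' @param n_micro Microsimulation cohort size per strategy evaluation.
#' @param cea Baseline [cea_params()]; the external draw overrides its
#'   sampled components, the schedule and discounting come from here.
#' @return Object of class `crc_psa`: data frame with one row per draw
#'   (`draw`, `cost_screen`, `qaly_screen`, `cost_none`, `qaly_none`,
#'   `dcost`, `dqaly`) and attributes `approach`, `n_micro`, `seed`.
#' @export
run_psa <- function(approach, calib, ext = fit_external_distributions(),
                    n_psa = 500, n_micro = 2000, seed = 1,
                    cea = cea_params()) {
  stopifnot(inherits(calib, "crc_calib"))
  pars <- draw_parameters(approach, calib, ext, n_psa, seed)
  set.seed(seed + 1L)
  sim_seeds <- sample.int(.Machine$integer.max - 2L, n_psa)
  rows <- vector("list", n_psa)
  for (i in seq_len(n_psa)) {
    cea_i <- cea
    for (p in colnames(pars$external)) cea_i[[p]] <- pars$external[i, p]
    th <- stats::setNames(pars$theta[i, ], colnames(pars$theta))
    r_s <- simulate_strategy(th, calib$theta_k, calib$lt, cea_i,
                             "colonoscopy_q10", n = n_micro,
                             seed = sim_seeds[i])
    r_n <- simulate_strategy(th, calib$theta_k, calib$lt, cea_i,
                             "no_screening", n = n_micro,
                             seed = sim_seeds[i])
    rows[[i]] <- data.frame(draw = i,
                            cost_screen = r_s$cost, qaly_screen = r_s$qaly,
                            cost_none = r_n$cost, qaly_none = r_n$qaly,
                            dcost = r_s$cost - r_n$cost,
                            dqaly = r_s$qaly - r_n$qaly)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("crc_psa", "data.frame"),
            approach = approach, n_micro = n_micro, seed = seed)
}
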