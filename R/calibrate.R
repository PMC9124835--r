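#' Bayesian calibration of the natural-history model
#'
#' Fits the nine unknown natural-history parameters to a set of age-binned
#' calibration targets by incremental mixture importance sampling
#' ([run_imis()]). The likelihood treats each target cell as Normal around
#' the expected model output computed from the deterministic cohort trace
#' (see [log_likelihood()]).
#'
#' @param targets A [generate_targets()] or [read_targets()] table.
#' @param priors A [crc_priors()] table.
#' @param theta_k Fixed parameters, [crc_fixed_params()].
#' @param lt Life table.
#' @param control IMIS settings, see [imis_control()]; use
#'   [imis_control_desk()] for a laptop-scale run.
#' @param seed Integer seed.
#' @param verbose Print sampler progress.
#' @return Object of class `crc_calib` with components `posterior` (a
#'   `crc_posterior`), `targets`, `theta_k`, `lt`, `priors`, `seed`, and
#'   `map`. Supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   `simulate` and `residuals`.
#' @examples
#' \donttest{
#' tg <- generate_targets(n_reps = 10, n_cancer = 20000, seed = 7)
#' fit <- crc_calibrate(tg, control = imis_control_desk(), seed = 7)
#' summary(fit)
#' }
#' @export
crc_calibrate <- function(targets, priors = crc_priors(),
                          theta_k = crc_fixed_params(),
                          lt = make_life_table(),
                          control = imis_control(), seed = 1,
                          verbose = FALSE) {
  stopifnot(inherits(targets, "data.frame"))
  loglik <- make_loglik(targets, theta_k, lt)
  post <- run_imis(loglik, priors, control, seed = seed, verbose = verbose)
  structure(list(posterior = post, targets = targets, theta_k = theta_k,
                 lt = lt, priors = priors, seed = seed,
                 map = map_estimate(post)),
            class = "crc_calib")
}

#' Posterior summary table and correlation matrix
#'
#' Per-parameter posterior mean, SD, MAP and equal-tailed 95% credible
#' interval (2.5th/97.5th percentiles of the resampled draws), plus the
#' 9x9 Pearson correlation matrix of the resampled draws.
#'
#' @param posterior A `crc_posterior` or `crc_calib`.
#' @return List of class `crc_posterior_summary`: `table` (data frame) and
#'   `correlation` (matrix).
#' @export
posterior_summary <- function(posterior) {
  p <- as_posterior(posterior)
  rs <- p$resample
  qs <- apply(rs, 2, stats::quantile, probs = c(0.025, 0.975))
  tab <- data.frame(param = colnames(rs),
                    mean = colMeans(rs),
                    sd = apply(rs, 2, stats::sd),
                    map = as.numeric(map_estimate(p)),
                    cri_lb = qs[1, ], cri_ub = qs[2, ],
                    row.names = NULL)
  structure(list(table = tab,
                 correlation = suppressWarnings(stats::cor(rs)),
                 ess = p$ess, n_unique = p$n_unique),
            class = "crc_posterior_summary")
}

#' @export
print.crc_posterior_summary <- function(x, digits = 4, ...) {
  cat("Posterior summary (", nrow(x$table), " parameters; ESS = ",
      round(x$ess, 1), ", unique resampled draws = ", x$n_unique, ")\n",
      sep = "")
  print(format(x$table, digits = digits), ...)
  invisible(x)
}

#' @export
print.crc_calib <- function(x, ...) {
  cat("Bayesian calibration of the CRC natural-history model (IMIS)\n")
  cat(sprintf("  targets: %d cells; draws evaluated: %d; ESS: %.1f after %d increments\n",
              nrow(x$targets), nrow(x$posterior$draws), x$posterior$ess,
              x$posterior$iterations))
  cat("  posterior means:\n")
  print(round(colMeans(x$posterior$resample), 5))
  invisible(x)
}

#' @export
summary.crc_calib <- function(object, ...) posterior_summary(object)

#' @export
#' @param type `"mean"` for posterior means, `"map"` for the MAP draw.
#' @rdname crc_calibrate
coef.crc_calib <- function(object, type = c("mean", "map"), ...) {
  type <- match.arg(type)
  if (type == "map") object$map else colMeans(object$posterior$resample)
}

#' @export
residuals.crc_calib <- function(object, ...) {
  phi <- model_outputs(
    cohort_trace(coef(object, "map"), object$theta_k, object$lt),
    attr(object$targets, "bins"))
  key <- function(d) paste(d$target_type, d$age_lo, d$age_hi)
  ph <- phi$value[match(key(object$targets), key(phi))]
  (object$targets$mean - ph) / object$targets$se
}

#' @export
simulate.crc_calib <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rs <- object$posterior$resample
  rs[sample.int(nrow(rs), nsim, replace = TRUE), , drop = FALSE]
}

#' @export
plot.crc_calib <- function(x, which = c("marginals", "pairs"), ...) {
  which <- match.arg(which)
  rs <- x$posterior$resample
  if (which == "pairs") {
    graphics::pairs(rs, pch = ".", ...)
  } else {
    op <- graphics::par(mfrow = c(3, 3), mar = c(4, 3, 2, 1))
    on.exit(graphics::par(op))
    for (j in colnames(rs)) {
      d <- stats::density(rs[, j])
      plot(d, main = j, xlab = "", ...)
    }
  }
  invisible(x)
}

#' Posterior predictive check of the calibration targets
#'
#' Evaluates the model outputs for draws from the posterior and summarises
#' each target cell by its posterior-predicted mean and 95% interval
#' (2.5th-97.5th percentile envelope). By default the deterministic cohort
#' trace is evaluated per draw; set `n_micro` for full-fidelity stochastic
#' microsimulation per draw.
#'
#' @param object A `crc_calib` fit.
#' @param n_draws Number of posterior draws to propagate.
#' @param n_micro If not `NULL`, microsimulation cohort size per draw.
#' @param seed Seed for draw selection (and microsimulation).
#' @param ... Unused.
#' @return Data frame: target cells with `mean`, `se`, posterior-predicted
#'   `pred_mean`, `pi_lb`, `pi_ub` and logical `inside`.
#' @export
predict.crc_calib <- function(object, n_draws = 500, n_micro = NULL,
                              seed = 1, ...) {
  posterior_predictive(object, n_draws = n_draws, n_micro = n_micro,
                       seed = seed)
}

#' @rdname predict.crc_calib
#' @export
posterior_predictive <- function(object, n_draws = 500, n_micro = NULL,
                                 seed = 1) {
  stopifnot(inherits(object, "crc_calib"))
  set.seed(seed)
  rs <- object$posterior$resample
  draws <- rs[sample.int(nrow(rs), min(n_draws, nrow(rs))), , drop = FALSE]
  bins <- attr(object$targets, "bins")
  vals <- apply(draws, 1, function(th) {
    th <- stats::setNames(th, colnames(rs))
    if (is.null(n_micro)) {
      model_outputs(cohort_trace(th, object$theta_k, object$lt), bins)$value
    } else {
      aggregate_outputs(simulate_individuals(
        th, object$theta_k, object$lt, n_micro,
        seed = sample.int(.Machine$integer.max - 1L, 1)), bins)$value
    }
  })
  tmpl <- model_outputs(cohort_trace(coef(object, "map"), object$theta_k,
                                     object$lt), bins)
  key <- function(d) paste(d$target_type, d$age_lo, d$age_hi)
  i <- match(key(object$targets), key(tmpl))
  out <- data.frame(object$targets[, c("target_type", "age_lo", "age_hi",
                                       "mean", "se")])
  out$pred_mean <- rowMeans(vals, na.rm = TRUE)[i]
  out$pi_lb <- apply(vals, 1, stats::quantile, 0.025, na.rm = TRUE)[i]
  out$pi_ub <- apply(vals, 1, stats::quantile, 0.975, na.rm = TRUE)[i]
  out$inside <- out$mean >= out$pi_lb & out$mean <= out$pi_ub
  out
}
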