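#' Calibration log-likelihood
#'
#' Normal likelihood of the targets given the model: each target cell
#' \eqn{y_{ta}} is assumed Normal with mean \eqn{\phi_{ta}(\theta)} — the
#' expected model output, computed from the deterministic [cohort_trace()]
#' — and standard deviation \eqn{\sigma_{ta}}, the target's replication
#' standard error. Log-densities are summed over all cells. Cells where the
#' model output is undefined (empty denominator) are dropped with a
#' warning.
#'
#' Using the deterministic trace (the expectation of the microsimulation)
#' makes the likelihood noise-free; a stochastic microsimulation estimate
#' of \eqn{\phi} can be substituted via `n_micro`.
#'
#' @inheritParams cohort_trace
#' @param targets A [generate_targets()] (or [read_targets()]) table.
#' @param n_micro If not `NULL`, estimate \eqn{\phi} by microsimulation of
#'   a cohort of this size (seeded by `micro_seed`) instead of the trace.
#' @param micro_seed Seed for the stochastic likelihood mode.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(theta_u, theta_k = crc_fixed_params(),
                           lt = make_life_table(), targets,
                           n_micro = NULL, micro_seed = 1) {
  bins <- attr(targets, "bins")
  if (is.null(bins)) bins <- bins_from_targets(targets)
  phi <- if (is.null(n_micro)) {
    model_outputs(cohort_trace(theta_u, theta_k, lt), bins)
  } else {
    aggregate_outputs(
      simulate_individuals(theta_u, theta_k, lt, n_micro, micro_seed), bins)
  }
  key <- function(d) paste(d$target_type, d$age_lo, d$age_hi)
  ph <- phi$value[match(key(targets), key(phi))]
  ok <- is.finite(ph)
  if (!all(ok))
    warning("model output undefined for ", sum(!ok),
            " target cell(s); dropped from the likelihood")
  sum(stats::dnorm(targets$mean[ok], ph[ok], targets$se[ok], log = TRUE))
}

# closure used by the sampler: theta row-vector -> log-likelihood
make_loglik <- function(targets, theta_k, lt) {
  force(targets); force(theta_k); force(lt)
  function(theta_u) log_likelihood(theta_u, theta_k, lt, targets)
}
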