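#' Prior distributions for the calibrated parameters
#'
#' Beta priors for the two proportions (adenoma prevalence and small-adenoma
#' share at age 50), lognormal priors for the Weibull onset-hazard scale and
#' shape and the five constant annual transition rates. Hyperparameters
#' `h1`/`h2` are (shape1, shape2) for beta and (meanlog, sdlog) for
#' lognormal.
#'
#' @return Data frame of class `crc_priors` with columns `param`, `family`,
#'   `h1`, `h2`.
#' @export
crc_priors <- function() {
  structure(data.frame(
    param = c("padeno", "psmall", "l", "gamma",
              "lambda2", "lambda3", "lambda4", "lambda5", "lambda6"),
    family = c("beta", "beta", rep("lognormal", 7)),
    h1 = c(3, 6, -11.97, 1.04, -3.45, -3.91, -1.15, -1.41, -0.78),
    h2 = c(8, 3, 0.59, 0.18, 0.59, 0.35, 0.23, 0.10, 0.22)),
    class = c("crc_priors", "data.frame"))
}

#' Log prior density
#'
#' Sum of the log prior densities of the parameters in the prior table;
#' `-Inf` outside the support. Families: `beta`, `lognormal`, `normal`.
#'
#' @param theta_u Named parameter vector (as [crc_params()]) or an
#'   N x d matrix of parameter rows.
#' @param priors A [crc_priors()]-shaped table.
#' @return Numeric scalar (or vector for a matrix input).
#' @export
log_prior <- function(theta_u, priors = crc_priors()) {
  th <- if (is.matrix(theta_u)) theta_u else
    matrix(unclass(theta_u), 1, dimnames = list(NULL, names(theta_u)))
  lp <- numeric(nrow(th))
  for (i in seq_len(nrow(priors))) {
    x <- th[, priors$param[i]]
    lp <- lp + switch(priors$family[i],
      beta = stats::dbeta(x, priors$h1[i], priors$h2[i], log = TRUE),
      lognormal = stats::dlnorm(x, priors$h1[i], priors$h2[i], log = TRUE),
      normal = stats::dnorm(x, priors$h1[i], priors$h2[i], log = TRUE),
      stop("unknown prior family: ", priors$family[i]))
  }
  lp[!is.finite(lp)] <- -Inf
  unname(lp)
}

#' Sample from the prior
#'
#' @param n Number of draws.
#' @param priors A [crc_priors()]-shaped table.
#' @return N x d matrix, columns in prior-table order.
#' @export
sample_prior <- function(n, priors = crc_priors()) {
  draws <- sapply(seq_len(nrow(priors)), function(i)
    switch(priors$family[i],
      beta = stats::rbeta(n, priors$h1[i], priors$h2[i]),
      lognormal = stats::rlnorm(n, priors$h1[i], priors$h2[i]),
      normal = stats::rnorm(n, priors$h1[i], priors$h2[i])))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- priors$param
  draws
}

#' Prior standard deviations
#'
#' Marginal prior SDs (closed form), used for the posterior-shrinkage check.
#'
#' @param priors A [crc_priors()]-shaped table.
#' @return Named numeric vector.
#' @export
prior_sd <- function(priors = crc_priors()) {
  s <- vapply(seq_len(nrow(priors)), function(i) {
    a <- priors$h1[i]; b <- priors$h2[i]
    switch(priors$family[i],
      beta = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
      lognormal = sqrt((exp(b^2) - 1) * exp(2 * a + b^2)),
      normal = b)
  }, numeric(1))
  names(s) <- priors$param
  s
}

# --- transformed (unconstrained) parameter space -------------------------
# The sampler runs on eta with a per-parameter link chosen by prior family
# (beta -> logit, lognormal -> log, normal -> identity) so that Gaussian
# mixture components respect the support.

to_unconstrained <- function(theta, priors = crc_priors()) {
  th <- if (is.matrix(theta)) theta else matrix(theta, 1)
  eta <- th
  for (i in seq_len(ncol(th)))
    eta[, i] <- switch(priors$family[i],
                       beta = stats::qlogis(th[, i]),
                       lognormal = log(th[, i]),
                       normal = th[, i])
  eta
}

from_unconstrained <- function(eta, priors = crc_priors()) {
  e <- if (is.matrix(eta)) eta else matrix(eta, 1)
  th <- e
  for (i in seq_len(ncol(e)))
    th[, i] <- switch(priors$family[i],
                      beta = stats::plogis(e[, i]),
                      lognormal = exp(e[, i]),
                      normal = e[, i])
  colnames(th) <- priors$param
  th
}

# log prior density of eta (includes the Jacobian |d theta / d eta|)
log_prior_unconstrained <- function(eta, priors = crc_priors()) {
  th <- from_unconstrained(eta, priors)
  ljac <- 0
  for (i in seq_len(ncol(th)))
    ljac <- ljac + switch(priors$family[i],
      beta = log(th[, i]) + log1p(-th[, i]),
      lognormal = log(th[, i]),
      normal = 0)
  log_prior(th, priors) + ljac
}
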