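#' Effective sample size of importance weights
#'
#' \eqn{ESS = 1 / \sum \tilde w_i^2} with \eqn{\tilde w} the normalized
#' weights; ranges from 1 (degenerate) to N (uniform).
#'
#' @param weights Non-negative weights, not all zero.
#' @return Scalar ESS.
#' @export
effective_sample_size <- function(weights) {
  if (any(weights < 0)) stop("negative weights")
  s <- sum(weights)
  if (s == 0) stop("all weights are zero")
  w <- weights / s
  1 / sum(w^2)
}

# log density of rows of x under N(mean, S), via Cholesky (internal;
# mvtnorm-free). chol_S = chol(S).
dmvnorm_log <- function(x, mean, chol_S) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  d <- ncol(x)
  z <- backsolve(chol_S, t(x) - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_S))) - 0.5 * colSums(z^2)
}

#' Control settings for the IMIS sampler
#'
#' @param n0 Initial number of prior draws.
#' @param b Draws added per iteration (also the neighbourhood size for the
#'   local covariance).
#' @param ess_target Stop once the effective sample size reaches this.
#' @param max_iters Secondary stop.
#' @param n_resample Size of the final resample (with replacement).
#' @param n_opt Number of optimizer starts for the optimization stage
#'   (components placed at local posterior maxima with inverse-Hessian
#'   covariance before incremental sampling begins); 0 disables it.
#' @return List of class `imis_control`.
#' @export
imis_control <- function(n0 = 5000, b = 500, ess_target = 5000,
                         max_iters = 100, n_resample = 5000, n_opt = 8) {
  stopifnot(n0 >= b, b >= 1, ess_target >= 1, max_iters >= 0, n_opt >= 0)
  structure(list(n0 = n0, b = b, ess_target = ess_target,
                 max_iters = max_iters, n_resample = n_resample,
                 n_opt = n_opt),
            class = "imis_control")
}

#' @describeIn imis_control Reduced sizes for desk-scale runs.
#' @export
imis_control_desk <- function() {
  imis_control(n0 = 1000, b = 100, ess_target = 1000, max_iters = 100,
               n_resample = 5000, n_opt = 6)
}

#' Incremental mixture importance sampling
#'
#' Samples from the posterior \eqn{p(\theta) L(\theta)} by iteratively
#' enriching an importance-sampling proposal. The algorithm starts from
#' `n0` prior draws. An optimization stage (as in the canonical IMIS
#' formulation) then runs quasi-Newton maximizations of the log-posterior
#' from the `n_opt` best initial draws and places mixture components at the
#' distinct local maxima found, each with covariance the inverse Hessian —
#' essential when the posterior concentrates on a narrow ridge, as the
#' weakly identified Weibull onset parameters do. Each subsequent
#' incremental iteration (i) computes importance weights proportional to
#' prior x likelihood over the current mixture proposal, (ii) centres a new
#' multivariate-normal component at the highest-weight draw with covariance
#' estimated from its `b` nearest neighbours (weight-adjusted), (iii) draws
#' `b` new points from that component and recomputes all weights under the
#' updated mixture. Iteration stops when the effective sample size reaches
#' `ess_target` or after `max_iters` increments; the weighted sample is
#' then resampled with replacement.
#'
#' Internally the sampler works on transformed parameters (logit for the
#' two proportions, log for the positive parameters) so Gaussian components
#' respect the support; densities are Jacobian-corrected. A near-singular
#' local covariance is ridge-regularized by `1e-8 * trace`.
#'
#' @param loglik Function mapping a named 9-parameter vector to its
#'   log-likelihood.
#' @param priors A [crc_priors()] table.
#' @param control An [imis_control()] list.
#' @param seed Integer seed.
#' @param verbose Print per-iteration ESS.
#' @return Object of class `crc_posterior`: list with `draws` (all
#'   evaluated parameter sets, original scale), `log_prior`, `log_lik`,
#'   `weights` (normalized), `resample` (matrix of `n_resample` rows),
#'   `resample_idx`, `ess`, `n_unique`, `iterations`, `priors`, `control`.
#' @export
run_imis <- function(loglik, priors = crc_priors(),
                     control = imis_control(), seed = 1, verbose = FALSE) {
  set.seed(seed)
  n0 <- control$n0; b <- control$b
  theta <- sample_prior(n0, priors)
  eta <- to_unconstrained(theta, priors)
  lp_eta <- log_prior_unconstrained(eta, priors)
  ll <- apply(theta, 1, loglik)
  centers <- list(); chols <- list()
  S0 <- stats::cov(eta)  # distance metric for neighbourhoods
  S0_inv <- solve(S0)
  b <- control$b

  # --- optimization stage: components at local posterior maxima ----------
  if (control$n_opt > 0) {
    negpost <- function(e) {
      lp <- log_prior_unconstrained(matrix(e, 1), priors)
      if (!is.finite(lp)) return(1e10)
      th <- drop(from_unconstrained(e, priors))
      if (any(!is.finite(th))) return(1e10)
      v <- lp + tryCatch(
        suppressWarnings(loglik(stats::setNames(th, priors$param))),
        error = function(err) -Inf)
      if (!is.finite(v)) 1e10 else -v
    }
    starts <- order(lp_eta + ll, decreasing = TRUE)[seq_len(control$n_opt)]
    for (s0 in starts) {
      # skip starts already inside an existing optimum component
      if (length(centers) &&
          min(vapply(centers, function(ct)
            stats::mahalanobis(matrix(eta[s0, ], 1), ct, S0_inv,
                               inverted = TRUE), numeric(1))) < 1) next
      opt <- tryCatch(
        stats::optim(eta[s0, ], negpost, method = "BFGS",
                     control = list(maxit = 200), hessian = TRUE),
        error = function(e) NULL)
      if (is.null(opt)) next
      H <- opt$hessian
      Sk <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
      ev <- if (is.null(Sk)) -1 else eigen(Sk, symmetric = TRUE,
                                           only.values = TRUE)$values
      if (is.null(Sk) || min(ev) <= 0)
        Sk <- S0 / 100  # fall back to a shrunk prior covariance
      ch <- tryCatch(chol(Sk), error = function(e) chol(S0 / 100))
      new_eta <- matrix(MASS::mvrnorm(b, opt$par, Sk), ncol = ncol(eta))
      centers[[length(centers) + 1L]] <- opt$par
      chols[[length(chols) + 1L]] <- ch
      new_theta <- from_unconstrained(new_eta, priors)
      eta <- rbind(eta, new_eta)
      theta <- rbind(theta, new_theta)
      lp_eta <- c(lp_eta, log_prior_unconstrained(new_eta, priors))
      ll <- c(ll, apply(new_theta, 1, loglik))
    }
  }
  comp_ld <- if (length(centers))
    vapply(seq_along(centers), function(k)
      dmvnorm_log(eta, centers[[k]], chols[[k]]), numeric(nrow(eta)))
  else matrix(numeric(0), nrow(eta), 0)
  comp_ld <- matrix(comp_ld, nrow = nrow(eta))
  iters <- 0L
  repeat {
    K <- length(centers)
    log_q <- if (K == 0) lp_eta else {
      M <- cbind(lp_eta + log(n0), comp_ld + log(b))
      apply(M, 1, logsumexp) - log(n0 + b * K)
    }
    log_w <- lp_eta + ll - log_q
    log_w[!is.finite(log_w)] <- -Inf
    if (all(log_w == -Inf)) stop("IMIS: zero total weight; check likelihood")
    w <- exp(log_w - logsumexp(log_w))
    ess <- 1 / sum(w^2)
    if (verbose)
      message(sprintf("IMIS iter %d: N=%d ESS=%.1f", iters, length(w), ess))
    if (ess >= control$ess_target || iters >= control$max_iters) break
    iters <- iters + 1L
    ctr <- eta[which.max(w), ]
    d2 <- stats::mahalanobis(eta, ctr, S0_inv, inverted = TRUE)
    nn <- order(d2)[seq_len(min(b, nrow(eta)))]
    wt <- w[nn] + 1 / length(w)
    Sk <- stats::cov.wt(eta[nn, , drop = FALSE], wt = wt / sum(wt),
                        center = ctr, method = "ML")$cov
    ch <- tryCatch(chol(Sk), error = function(e) NULL)
    if (is.null(ch) || rcond(Sk) < 1e-12) {
      Sk <- Sk + diag(1e-8 * sum(diag(Sk)), ncol(Sk))
      ch <- chol(Sk)
    }
    new_eta <- matrix(MASS::mvrnorm(b, ctr, Sk), ncol = ncol(eta))
    # extend caches: new component over all points, all components over new
    comp_ld <- cbind(comp_ld, dmvnorm_log(eta, ctr, ch))
    centers[[K + 1L]] <- ctr
    chols[[K + 1L]] <- ch
    new_ld <- vapply(seq_len(K + 1L), function(k)
      dmvnorm_log(new_eta, centers[[k]], chols[[k]]),
      numeric(nrow(new_eta)))
    comp_ld <- rbind(comp_ld, matrix(new_ld, nrow = nrow(new_eta)))
    new_theta <- from_unconstrained(new_eta, priors)
    eta <- rbind(eta, new_eta)
    theta <- rbind(theta, new_theta)
    lp_eta <- c(lp_eta, log_prior_unconstrained(new_eta, priors))
    ll <- c(ll, apply(new_theta, 1, loglik))
  }
  idx <- sample.int(length(w), control$n_resample, replace = TRUE, prob = w)
  structure(list(draws = theta,
                 log_prior = log_prior(theta, priors), log_lik = ll,
                 weights = w,
                 resample = theta[idx, , drop = FALSE], resample_idx = idx,
                 ess = ess, n_unique = length(unique(idx)),
                 iterations = iters, priors = priors, control = control),
            class = "crc_posterior")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Maximum-a-posteriori estimate
#'
#' The evaluated draw with the highest posterior density
#' (log-prior + log-likelihood); ties broken by first occurrence.
#'
#' @param posterior A `crc_posterior` (or [crc_calibrate()] fit).
#' @return Named 9-parameter vector.
#' @export
map_estimate <- function(posterior) {
  p <- as_posterior(posterior)
  if (!length(p$log_lik)) stop("empty posterior sample")
  lp <- p$log_prior + p$log_lik
  p$draws[which.max(lp), ]
}

as_posterior <- function(x) {
  if (inherits(x, "crc_calib")) x$posterior
  else if (inherits(x, "crc_posterior")) x
  else stop("expected a crc_posterior or crc_calib object")
}
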