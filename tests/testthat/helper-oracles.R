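# Independent oracles and shared fixtures.

# truncated-series matrix exponential with scaling and squaring:
# the series sum_{k<=K} A^k / k! is evaluated at A = tQ / 2^s (s chosen so
# the scaled norm is < 1/2, avoiding cancellation) and squared back up
series_expm <- function(Q, t = 1, K = 30) {
  A <- t * Q
  s <- max(0, ceiling(log2(max(norm(A, "I"), 2^-20)) + 1))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(K)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# random valid generator matrix on the model's sparsity pattern
random_intensity <- function() {
  theta <- crc_params(padeno = runif(1, 0.05, 0.5),
                      psmall = runif(1, 0.3, 0.9),
                      l = exp(runif(1, -14, -10)),
                      gamma = runif(1, 1.5, 3.5),
                      lambda2 = runif(1, 0.005, 0.1),
                      lambda3 = runif(1, 0.005, 0.1),
                      lambda4 = runif(1, 0.05, 0.8),
                      lambda5 = runif(1, 0.05, 0.8),
                      lambda6 = runif(1, 0.05, 0.9))
  build_intensity_matrix(theta, crc_fixed_params(),
                         mu_a = runif(1, 0, 0.3),
                         a = sample(50:99, 1))
}

# parameter set with (effectively) no disease dynamics
inert_params <- function(padeno = 1e-12) {
  crc_params(padeno = padeno, psmall = 0.5, l = 1e-300, gamma = 1,
             lambda2 = 1e-300, lambda3 = 1e-300, lambda4 = 1e-300,
             lambda5 = 1e-300, lambda6 = 1e-300)
}

zero_mortality_lt <- function() make_life_table(A = 0, B = 0, k = 0)

# expensive shared fixtures, built once per test run
.fix <- new.env(parent = emptyenv())

acceptance_targets <- function() {
  if (is.null(.fix$targets))
    .fix$targets <- generate_targets(n_reps = 30, seed = 1)
  .fix$targets
}

acceptance_fit <- function() {
  if (is.null(.fix$fit))
    .fix$fit <- crc_calibrate(acceptance_targets(),
                              control = imis_control_desk(), seed = 1)
  .fix$fit
}

acceptance_psa <- function() {
  if (is.null(.fix$psa)) {
    ext <- fit_external_distributions()
    .fix$psa <- lapply(stats::setNames(uq_approaches, uq_approaches),
                       function(ap) run_psa(ap, acceptance_fit(), ext,
                                            n_psa = 150, n_micro = 2000,
                                            seed = 1))
  }
  .fix$psa
}
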