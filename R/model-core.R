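#' Weibull hazard for adenoma onset
#'
#' Age-dependent rate of the normal -> small adenoma transition,
#' \eqn{\lambda_1(a) = l \gamma a^{\gamma - 1}}.
#'
#' @param a Age in years (non-negative, may be a vector).
#' @param l Weibull scale parameter (> 0).
#' @param gamma Weibull shape parameter (> 0).
#' @return Hazard rate(s) per year.
#' @examples
#' weibull_hazard(50, 2.86e-06, 2.78)
#' @export
weibull_hazard <- function(a, l, gamma) {
  if (any(a < 0)) stop("age must be non-negative")
  if (l <= 0 || gamma <= 0) stop("l and gamma must be positive")
  l * gamma * a^(gamma - 1)
}

#' Age-dependent transition intensity matrix
#'
#' Builds the 9x9 generator Q(a) of the continuous-time natural-history
#' process at age `a`. Off-diagonal entries are the annual transition rates;
#' every alive state is also subject to the other-cause mortality rate
#' `mu_a`; diagonals make rows sum to zero; the two death states are
#' absorbing (zero rows).
#'
#' @param theta_u [crc_params()] vector.
#' @param theta_k [crc_fixed_params()] vector.
#' @param mu_a Other-cause mortality rate at age `a` (per year, >= 0).
#' @param a Age in years.
#' @param onset_hr Hazard ratio multiplying the adenoma-onset rate
#'   \eqn{\lambda_1(a)}; 1 except after polypectomy (elevated recurrence).
#' @return 9x9 matrix with `crc_states` dimnames.
#' @export
build_intensity_matrix <- function(theta_u, theta_k, mu_a, a, onset_hr = 1) {
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (onset_hr <= 0) stop("onset_hr must be > 0")
  Q <- matrix(0, 9, 9, dimnames = list(crc_states, crc_states))
  lam1 <- onset_hr * weibull_hazard(a, theta_u[["l"]], theta_u[["gamma"]])
  Q[1, 2] <- lam1
  Q[2, 3] <- theta_u[["lambda2"]]
  Q[3, 4] <- theta_u[["lambda3"]]
  Q[4, 5] <- theta_u[["lambda4"]]
  Q[4, 6] <- theta_u[["lambda5"]]
  Q[5, 7] <- theta_u[["lambda6"]]
  Q[6, 8] <- theta_k[["lambda7"]]
  Q[7, 8] <- theta_k[["lambda8"]]
  Q[.ALIVE, 9] <- mu_a
  diag(Q) <- -rowSums(Q)
  Q
}

#' Annual transition probability matrix
#'
#' Discretizes a transition intensity matrix to cycle length `t` via the
#' matrix exponential, \eqn{P(a, t) = \exp(t Q(a))} (the solution of the
#' Kolmogorov forward equations). The exponential permits transitions across
#' several health states within a single cycle, e.g. small adenoma ->
#' preclinical CRC in one year.
#'
#' @param Q 9x9 (or n x n) intensity matrix: non-negative off-diagonals,
#'   rows summing to zero.
#' @param t Cycle length in years (default 1).
#' @return Row-stochastic matrix of the same dimension.
#' @export
transition_probability_matrix <- function(Q, t = 1) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), t >= 0)
  off <- Q
  diag(off) <- 0
  if (any(off < 0)) stop("Q has negative off-diagonal entries")
  if (max(abs(rowSums(Q))) > 1e-8) stop("Q rows must sum to zero")
  P <- as.matrix(Matrix::expm(t * Q))
  # guard against tiny negative round-off
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Initial state distribution of the 50-year-old cohort
#'
#' The cohort starts with adenoma prevalence `padeno` (split `psmall` /
#' `1 - psmall` between small and large), the fixed preclinical early/late
#' CRC prevalences, and the remainder in the normal state.
#'
#' @inheritParams build_intensity_matrix
#' @return Numeric 9-vector of proportions summing to 1.
#' @export
initial_state_distribution <- function(theta_u, theta_k) {
  v <- numeric(9)
  names(v) <- crc_states
  v["small_adenoma"] <- theta_u[["padeno"]] * theta_u[["psmall"]]
  v["large_adenoma"] <- theta_u[["padeno"]] * (1 - theta_u[["psmall"]])
  v["preclin_early_crc"] <- theta_k[["p_preclin_early_50"]]
  v["preclin_late_crc"] <- theta_k[["p_preclin_late_50"]]
  v["normal"] <- 1 - sum(v)
  if (v["normal"] < 0)
    stop("invalid parameters: initial prevalences exceed 1")
  v
}

# Transition matrices for a span of ages (internal workhorse).
# Returns a list of 9x9 P matrices, one per age in `ages`.
transition_matrices <- function(theta_u, theta_k, lt, ages, onset_hr = 1) {
  mu <- life_table_rate(lt, ages)
  lapply(seq_along(ages), function(i) {
    Q <- build_intensity_matrix(theta_u, theta_k, mu[i], ages[i], onset_hr)
    transition_probability_matrix(Q, 1)
  })
}

#' Deterministic cohort trace
#'
#' Propagates the expected state-occupancy of the cohort from `age_start`
#' through `age_end` in annual cycles: occupancy at age a+1 equals the
#' occupancy at age a times P(a). Also records the expected annual flows
#' into the clinical states (new clinical early/late CRC) from non-clinical
#' states, and the person-years at risk (alive without clinical CRC). This
#' is the expectation of the microsimulation and is used as the model mean
#' in the calibration likelihood.
#'
#' @inheritParams build_intensity_matrix
#' @param lt Life table from [make_life_table()] or [read_life_table()].
#' @param age_start,age_end Integer ages bounding the trace (default 50-100).
#' @return Object of class `crc_trace`: list with `occupancy`
#'   (ages x states matrix), `flows` (per-age new clinical early/late, as
#'   cohort proportions), `at_risk` (per-age proportion alive without
#'   clinical CRC) and `ages`.
#' @export
cohort_trace <- function(theta_u, theta_k, lt,
                         age_start = 50, age_end = 100) {
  stopifnot(age_end > age_start)
  ages <- age_start:age_end
  cyc <- ages[-length(ages)]
  Ps <- transition_matrices(theta_u, theta_k, lt, cyc)
  occ <- matrix(0, length(ages), 9, dimnames = list(ages, crc_states))
  occ[1, ] <- initial_state_distribution(theta_u, theta_k)
  flows <- matrix(0, length(cyc), 2,
                  dimnames = list(cyc, c("new_clin_early", "new_clin_late")))
  for (i in seq_along(cyc)) {
    P <- Ps[[i]]
    x <- occ[i, ]
    occ[i + 1, ] <- x %*% P
    # incidence: non-clinical at age a, clinical at age a+1
    flows[i, 1] <- sum(x[.AT_RISK] * P[.AT_RISK, .S$clin_early_crc])
    flows[i, 2] <- sum(x[.AT_RISK] * P[.AT_RISK, .S$clin_late_crc])
  }
  structure(list(occupancy = occ, flows = flows,
                 at_risk = rowSums(occ[, .AT_RISK, drop = FALSE]),
                 ages = ages),
            class = "crc_trace")
}

#' Default age bins for model outputs and calibration targets
#'
#' Adenoma prevalence and the proportion of small adenomas are evaluated
#' cross-sectionally at single ages; stage-specific clinical CRC incidence
#' over inclusive multi-year age bins.
#'
#' @param prev_ages Ages for the adenoma targets.
#' @param inc_lo Lower edges of the incidence bins.
#' @param inc_width Width of each incidence bin in years (bin is
#'   `[lo, lo + width - 1]`, inclusive).
#' @return Object of class `crc_age_bins`.
#' @export
crc_age_bins <- function(prev_ages = c(50, 55, 60, 65, 70),
                         inc_lo = seq(52, 82, by = 5),
                         inc_width = 5) {
  structure(list(prev_ages = prev_ages,
                 inc_lo = inc_lo, inc_hi = inc_lo + inc_width - 1),
            class = "crc_age_bins")
}

#' Expected model outputs on an age-bin scheme
#'
#' Reduces a cohort trace to the four calibration-target quantities:
#' adenoma prevalence (small + large occupancy over alive occupancy) and
#' the proportion of small adenomas among carriers at single ages, and
#' clinical CRC incidence per 100,000 person-years at risk (alive without
#' clinical CRC), by stage, aggregated over each incidence bin.
#'
#' Cells with an empty denominator (no carriers, no one at risk) are
#' returned as `NA` rather than silently zero.
#'
#' @param trace A [cohort_trace()] result.
#' @param bins A [crc_age_bins()] scheme.
#' @return Data frame with columns `target_type` (one of `adenoma_prev`,
#'   `prop_small`, `inc_early`, `inc_late`), `age_lo`, `age_hi`, `value`.
#' @export
model_outputs <- function(trace, bins = crc_age_bins()) {
  occ <- trace$occupancy
  ages <- trace$ages
  if (any(!(bins$prev_ages %in% ages)) ||
      any(bins$inc_lo < min(ages)) || any(bins$inc_hi > max(ages) - 1))
    stop("age bins outside the trace range")
  out <- list()
  for (a in bins$prev_ages) {
    i <- match(a, ages)
    alive <- sum(occ[i, .ALIVE])
    aden <- sum(occ[i, .ADENOMA])
    small <- occ[i, .S$small_adenoma]
    out[[length(out) + 1L]] <- data.frame(
      target_type = c("adenoma_prev", "prop_small"),
      age_lo = a, age_hi = a,
      value = c(if (alive > 0) aden / alive else NA_real_,
                if (aden > 0) small / aden else NA_real_))
  }
  cyc <- as.integer(rownames(trace$flows))
  for (b in seq_along(bins$inc_lo)) {
    sel <- cyc >= bins$inc_lo[b] & cyc <= bins$inc_hi[b]
    py <- sum(trace$at_risk[match(cyc[sel], ages)])
    out[[length(out) + 1L]] <- data.frame(
      target_type = c("inc_early", "inc_late"),
      age_lo = bins$inc_lo[b], age_hi = bins$inc_hi[b],
      value = if (py > 0) 1e5 * colSums(trace$flows[sel, , drop = FALSE]) / py
              else c(NA_real_, NA_real_))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
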