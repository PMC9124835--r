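#' Individual-level microsimulation of the natural history
#'
#' Simulates annual state paths for `n` individuals from `age_start` to
#' `age_end`. Each individual starts in a state drawn from
#' [initial_state_distribution()] and transitions each year by a single
#' categorical draw from the row of the annual transition matrix P(a) for
#' their current state — the matrix exponential discretization means one
#' draw can move an individual across several health states in a year.
#'
#' An optional `hook` is called at the start of every cycle, before the
#' transition draw, and may relocate individuals (screening detection,
#' polypectomy) and update per-person bookkeeping. The hook signature is
#' `function(age, state, env)` returning the (possibly modified) integer
#' state vector; `env` is an environment owned by the caller, in which the
#' hook may keep risk classes, schedules and accrued costs. Individuals in
#' risk class 1 (low) or 2 (high) after polypectomy face the adenoma-onset
#' hazard multiplied by the corresponding entry of `onset_hr`.
#'
#' Reproducibility contract: with the same `seed` (and same hook
#' randomness) the returned paths are identical. Exactly `n` transition
#' uniforms are consumed per cycle regardless of how many individuals are
#' alive, so two runs with the same seed but different interventions share
#' common random numbers.
#'
#' @inheritParams cohort_trace
#' @param n Number of individuals.
#' @param seed Integer seed for the transition stream.
#' @param hook Optional per-cycle intervention callback (see Details).
#' @param hook_env Environment passed to the hook.
#' @param onset_hr Hazard ratios for risk classes (none, low, high).
#' @return Object of class `crc_paths`: list with `states` (n x ages
#'   integer matrix of state indices *after* any hook relocation), `ages`,
#'   and `n`.
#' @export
simulate_individuals <- function(theta_u, theta_k, lt, n, seed,
                                 age_start = 50, age_end = 100,
                                 hook = NULL, hook_env = NULL,
                                 onset_hr = c(1, 2, 3)) {
  stopifnot(n >= 1, age_end > age_start)
  ages <- age_start:age_end
  cyc <- ages[-length(ages)]
  # transition matrices per risk class; cumulative rows for inverse-CDF draws
  risk_levels <- if (is.null(hook)) 1L else seq_along(onset_hr)
  cumP <- lapply(risk_levels, function(r) {
    Ps <- transition_matrices(theta_u, theta_k, lt, cyc, onset_hr[r])
    lapply(Ps, function(P) t(apply(P, 1, cumsum)))
  })
  set.seed(seed)
  init <- initial_state_distribution(theta_u, theta_k)
  state <- 1L + findInterval(stats::runif(n), cumsum(init)[-9])
  states <- matrix(0L, n, length(ages),
                   dimnames = list(NULL, ages))
  for (j in seq_along(cyc)) {
    a <- cyc[j]
    if (!is.null(hook)) state <- hook(a, state, hook_env)
    states[, j] <- state
    u <- stats::runif(n)  # fixed-size block: common random numbers
    risk <- if (is.null(hook) || is.null(hook_env$risk)) rep(0L, n)
            else hook_env$risk
    newstate <- state
    for (r in risk_levels) {
      for (s in .ALIVE) {
        idx <- which(state == s & risk == r - 1L)
        if (!length(idx)) next
        cp <- cumP[[r]][[j]][s, ]
        newstate[idx] <- 1L + findInterval(u[idx], cp[-9])
      }
    }
    state <- newstate
  }
  if (!is.null(hook)) state <- hook(age_end, state, hook_env)
  states[, length(ages)] <- state
  structure(list(states = states, ages = ages, n = n), class = "crc_paths")
}

#' Aggregate simulated paths to model outputs
#'
#' Computes the same quantities as [model_outputs()] from simulated
#' individual paths, with identical conventions: prevalence and the small
#' fraction are cross-sectional among the alive at single ages; incidence
#' counts individuals non-clinical at age a and clinical at a+1, per
#' 100,000 person-years at risk. Bins with an empty denominator yield `NA`.
#'
#' @param paths A [simulate_individuals()] result.
#' @param bins A [crc_age_bins()] scheme.
#' @return Data frame as [model_outputs()], plus attribute `n`.
#' @export
aggregate_outputs <- function(paths, bins = crc_age_bins()) {
  st <- paths$states
  ages <- paths$ages
  if (nrow(st) == 0L) stop("empty path collection")
  out <- list()
  for (a in bins$prev_ages) {
    i <- match(a, ages)
    if (is.na(i)) stop("age bins outside simulated range")
    alive <- sum(st[, i] <= 7L)
    aden <- sum(st[, i] == 2L | st[, i] == 3L)
    small <- sum(st[, i] == 2L)
    out[[length(out) + 1L]] <- data.frame(
      target_type = c("adenoma_prev", "prop_small"),
      age_lo = a, age_hi = a,
      value = c(if (alive > 0) aden / alive else NA_real_,
                if (aden > 0) small / aden else NA_real_))
  }
  for (b in seq_along(bins$inc_lo)) {
    cols <- match(bins$inc_lo[b]:bins$inc_hi[b], ages)
    if (anyNA(cols) || max(cols) >= length(ages))
      stop("incidence bins outside simulated range")
    ev_e <- 0; ev_l <- 0; py <- 0
    for (i in cols) {
      atrisk <- st[, i] <= 5L
      py <- py + sum(atrisk)
      ev_e <- ev_e + sum(atrisk & st[, i + 1L] == 6L)
      ev_l <- ev_l + sum(atrisk & st[, i + 1L] == 7L)
    }
    out[[length(out) + 1L]] <- data.frame(
      target_type = c("inc_early", "inc_late"),
      age_lo = bins$inc_lo[b], age_hi = bins$inc_hi[b],
      value = if (py > 0) 1e5 * c(ev_e, ev_l) / py else c(NA_real_, NA_real_))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "n") <- paths$n
  out
}
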