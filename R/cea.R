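#' Cost-effectiveness analysis parameters
#'
#' External (non-calibrated) parameters of the screening cost-effectiveness
#' analysis: colonoscopy test characteristics, post-polypectomy recurrence
#' hazard ratios, costs, utilities and the screening/surveillance schedule.
#' Defaults are the point values of the study design. The discount rate is
#' applied to both costs and QALYs from age 50; it is not part of the
#' source parameter table and defaults to 3%/year (set to 0 to disable) —
#' absolute EVPI magnitudes depend on it.
#'
#' @param sens_small Colonoscopy sensitivity for small adenomas.
#' @param sens_large_crc Sensitivity for large adenomas and (preclinical) CRC.
#' @param spec Specificity in the normal state (carried for completeness;
#'   false positives incur no cost beyond the already-counted colonoscopy).
#' @param hr_low_risk Adenoma-onset hazard ratio after small-adenoma
#'   polypectomy (low-risk surveillance class).
#' @param hr_high_risk Onset hazard ratio after large-adenoma polypectomy.
#' @param cost_colonoscopy Cost per colonoscopy ($).
#' @param cost_early_annual Annual cost of clinical early-stage CRC ($).
#' @param cost_late_annual Annual cost of clinical late-stage CRC ($).
#' @param util_preclin Utility weight of preclinical CRC.
#' @param util_early Utility weight of clinical early-stage CRC.
#' @param util_late Utility weight of clinical late-stage CRC.
#' @param discount_rate Annual discount rate for costs and QALYs.
#' @param screen_start,screen_stop First/last age eligible for screening or
#'   surveillance colonoscopy.
#' @param screen_interval Routine screening interval (years).
#' @param surveil_small,surveil_large Surveillance intervals after a
#'   small/large adenoma finding (years).
#' @return List of class `cea_params`.
#' @export
cea_params <- function(sens_small = 0.773, sens_large_crc = 0.950,
                       spec = 0.868,
                       hr_low_risk = 2, hr_high_risk = 3,
                       cost_colonoscopy = 10000,
                       cost_early_annual = 21524,
                       cost_late_annual = 37000,
                       util_preclin = 1.000, util_early = 0.855,
                       util_late = 0.300,
                       discount_rate = 0.03,
                       screen_start = 50, screen_stop = 85,
                       screen_interval = 10,
                       surveil_small = 5, surveil_large = 3) {
  p <- as.list(environment())
  stopifnot(p$sens_small >= 0, p$sens_small <= 1,
            p$sens_large_crc >= 0, p$sens_large_crc <= 1,
            p$spec >= 0, p$spec <= 1,
            p$hr_low_risk >= 1, p$hr_high_risk >= 1,
            p$cost_colonoscopy >= 0, p$cost_early_annual >= 0,
            p$cost_late_annual >= 0,
            p$util_preclin >= 0, p$util_preclin <= 1,
            p$util_early >= 0, p$util_early <= 1,
            p$util_late >= 0, p$util_late <= 1,
            p$discount_rate >= 0)
  structure(p, class = "cea_params")
}

#' Simulate a screening strategy
#'
#' Runs the microsimulation under `no_screening` or 10-yearly colonoscopy
#' (`colonoscopy_q10`) and accrues per-person discounted costs and QALYs.
#'
#' Screening logic, per due colonoscopy (ages `screen_start` to
#' `screen_stop`, merged screening/surveillance clock): a small adenoma is
#' detected with probability `sens_small` and removed (polypectomy: back to
#' normal, low-risk class, surveillance in `surveil_small` years); a large
#' adenoma with probability `sens_large_crc` (high-risk class, surveillance
#' in `surveil_large` years); preclinical CRC is detected with probability
#' `sens_large_crc` and converts to the clinical state of the same stage.
#' After a negative exam the routine `screen_interval`-year clock resumes.
#' Post-polypectomy risk classes are absorbing at the higher class and
#' multiply the adenoma-onset hazard by the corresponding hazard ratio.
#'
#' Accrual per annual cycle, for individuals alive at the end of the cycle:
#' stage utilities and annual CRC care costs of the (post-test) state,
#' discounted from age 50. Each performed colonoscopy adds its cost at the
#' exam age. Individuals dying within a cycle accrue nothing that cycle.
#'
#' With equal `seed` the two strategies share common random numbers (same
#' initial states and transition uniforms), which sharply reduces the
#' variance of incremental outcomes.
#'
#' @inheritParams cohort_trace
#' @param cea A [cea_params()] list.
#' @param strategy `"no_screening"` or `"colonoscopy_q10"`.
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return Object of class `crc_strategy_result`: list with `strategy`,
#'   `cost` and `qaly` (per-person means), `cost_i`/`qaly_i` (per-person
#'   vectors), `n_colonoscopy` (mean per person), `n_clin_late` (count of
#'   individuals ever entering clinical late-stage CRC), `n`, `seed`.
#' @export
simulate_strategy <- function(theta_u, theta_k = crc_fixed_params(),
                              lt = make_life_table(), cea = cea_params(),
                              strategy = c("no_screening", "colonoscopy_q10"),
                              n = 10000, seed = 1) {
  strategy <- match.arg(strategy)
  ages <- 50:100
  screening <- strategy == "colonoscopy_q10"
  env <- new.env(parent = emptyenv())
  env$risk <- rep(0L, n)
  env$colo_cost <- rep(0, n)
  env$n_colo <- 0
  hook <- NULL
  if (screening) {
    # separate RNG stream for detection draws so the transition stream
    # stays aligned with the no-screening arm (common random numbers)
    set.seed(seed + 500001L)
    env$det_u <- matrix(stats::runif(n * length(ages)), n, length(ages))
    env$next_due <- rep(cea$screen_start, n)
    disc <- (1 + cea$discount_rate)^-(ages - 50)
    hook <- function(a, state, e) {
      j <- match(a, ages)
      due <- which(e$next_due <= a & a <= cea$screen_stop &
                     state %in% 1:5)
      if (!length(due)) return(state)
      e$colo_cost[due] <- e$colo_cost[due] + disc[j] * cea$cost_colonoscopy
      e$n_colo <- e$n_colo + length(due)
      u <- e$det_u[due, j]
      s <- state[due]
      hit_small <- s == 2L & u < cea$sens_small
      hit_large <- s == 3L & u < cea$sens_large_crc
      hit_pe <- s == 4L & u < cea$sens_large_crc
      hit_pl <- s == 5L & u < cea$sens_large_crc
      state[due[hit_small]] <- 1L
      state[due[hit_large]] <- 1L
      state[due[hit_pe]] <- 6L
      state[due[hit_pl]] <- 7L
      e$risk[due[hit_small]] <- pmax(e$risk[due[hit_small]], 1L)
      e$risk[due[hit_large]] <- 2L
      nd <- rep(cea$screen_interval, length(due))
      nd[hit_small] <- cea$surveil_small
      nd[hit_large] <- cea$surveil_large
      e$next_due[due] <- a + nd
      state
    }
  }
  paths <- simulate_individuals(theta_u, theta_k, lt, n, seed,
                                hook = hook, hook_env = env,
                                onset_hr = c(1, cea$hr_low_risk,
                                             cea$hr_high_risk))
  st <- paths$states
  util <- c(1, 1, 1, cea$util_preclin, cea$util_preclin,
            cea$util_early, cea$util_late, 0, 0)
  ann_cost <- c(0, 0, 0, 0, 0, cea$cost_early_annual, cea$cost_late_annual,
                0, 0)
  disc <- (1 + cea$discount_rate)^-(ages - 50)
  qaly <- rep(0, n); cost <- env$colo_cost
  for (j in seq_len(ncol(st) - 1L)) {
    alive_next <- st[, j + 1L] <= 7L
    qaly <- qaly + disc[j] * util[st[, j]] * alive_next
    cost <- cost + disc[j] * ann_cost[st[, j]] * alive_next
  }
  ever_late <- sum(apply(st == 7L, 1, any))
  structure(list(strategy = strategy,
                 cost = mean(cost), qaly = mean(qaly),
                 cost_i = cost, qaly_i = qaly,
                 n_colonoscopy = env$n_colo / n,
                 n_clin_late = ever_late, n = n, seed = seed),
            class = "crc_strategy_result")
}

#' Incremental cost and QALYs of screening vs no screening
#'
#' @param r_screen,r_none [simulate_strategy()] results from the same `n`
#'   and seed policy.
#' @return List of class `crc_incremental`: `delta_cost`, `delta_qaly`.
#' @export
incremental_outcomes <- function(r_screen, r_none) {
  stopifnot(inherits(r_screen, "crc_strategy_result"),
            inherits(r_none, "crc_strategy_result"))
  if (r_screen$n != r_none$n)
    stop("strategy results come from different cohort sizes")
  structure(list(delta_cost = r_screen$cost - r_none$cost,
                 delta_qaly = r_screen$qaly - r_none$qaly),
            class = "crc_incremental")
}
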