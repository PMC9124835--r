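#' Point values and ranges of the external CEA parameters
#'
#' The printed value (mean) and 95% equal-tailed interval of each external
#' parameter, with its distribution family: beta for the test
#' characteristics, lognormal for hazard ratios, costs and utilities.
#'
#' @return Data frame with columns `name`, `value`, `lo`, `hi`, `family`.
#' @export
cea_param_table <- function() {
  data.frame(
    name = c("sens_small", "sens_large_crc", "spec",
             "hr_low_risk", "hr_high_risk",
             "cost_colonoscopy", "cost_early_annual", "cost_late_annual",
             "util_preclin", "util_early", "util_late"),
    value = c(0.773, 0.950, 0.868, 2, 3, 10000, 21524, 37000,
              1.000, 0.855, 0.300),
    lo = c(0.734, 0.920, 0.855, 1, 2, 9000, 20000, 35000,
           0.980, 0.700, 0.200),
    hi = c(0.808, 0.990, 0.880, 3, 4, 11000, 23000, 39000,
           1.000, 0.900, 0.400),
    family = c("beta", "beta", "beta",
               rep("lognormal", 5), rep("lognormal", 3)))
}

#' Fit distributions to external parameters from value and range
#'
#' For each external parameter, fits the stated family so that the mean is
#' anchored at the printed value and the 2.5th/97.5th percentiles
#' reproduce the printed 95% equal-tailed interval by least squares (the
#' problem is over-determined, so the percentile mismatch is minimised
#' subject to the mean anchor). Beta distributions are parametrised by
#' concentration at fixed mean, lognormals by sigma at fixed mean. A
#' degenerate range (`lo == hi`) yields a point mass. Utility samples are
#' capped at 1 when drawn (a utility weight cannot exceed perfect health).
#'
#' @param table Parameter table as [cea_param_table()].
#' @return Object of class `crc_external_dists`: the table with fitted
#'   hyperparameter columns `par1`, `par2` (shape1/shape2 or
#'   meanlog/sdlog; `NA` for point masses).
#' @export
fit_external_distributions <- function(table = cea_param_table()) {
  stopifnot(all(c("name", "value", "lo", "hi", "family") %in% names(table)))
  if (any(table$lo > table$hi)) stop("range lower bound exceeds upper")
  if (any(table$value < table$lo | table$value > table$hi))
    stop("value outside its range")
  table$par1 <- NA_real_
  table$par2 <- NA_real_
  for (i in seq_len(nrow(table))) {
    m <- table$value[i]; lo <- table$lo[i]; hi <- table$hi[i]
    if (lo == hi) next  # point mass
    if (table$family[i] == "beta") {
      obj <- function(logk) {
        k <- exp(logk)
        (stats::qbeta(0.025, m * k, (1 - m) * k) - lo)^2 +
          (stats::qbeta(0.975, m * k, (1 - m) * k) - hi)^2
      }
      k <- exp(stats::optimize(obj, c(log(2), log(1e6)))$minimum)
      table$par1[i] <- m * k
      table$par2[i] <- (1 - m) * k
    } else {
      obj <- function(logs) {
        s <- exp(logs)
        mu <- log(m) - s^2 / 2
        (stats::qlnorm(0.025, mu, s) - lo)^2 +
          (stats::qlnorm(0.975, mu, s) - hi)^2
      }
      s <- exp(stats::optimize(obj, c(log(1e-4), log(2)))$minimum)
      table$par1[i] <- log(m) - s^2 / 2
      table$par2[i] <- s
    }
  }
  structure(table, class = c("crc_external_dists", "data.frame"))
}

#' Sample the external parameters
#'
#' @param ext A [fit_external_distributions()] object.
#' @param n Number of draws.
#' @return n x k matrix, columns named after the parameters. Utility
#'   draws are capped at 1.
#' @export
sample_external <- function(ext, n) {
  draws <- sapply(seq_len(nrow(ext)), function(i) {
    if (is.na(ext$par1[i])) return(rep(ext$value[i], n))
    x <- if (ext$family[i] == "beta")
      stats::rbeta(n, ext$par1[i], ext$par2[i])
    else
      stats::rlnorm(n, ext$par1[i], ext$par2[i])
    if (startsWith(ext$name[i], "util_")) x <- pmin(x, 1)
    x
  })
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- ext$name
  draws
}

#' Moment-matched beta distribution
#'
#' Solves for `(shape1, shape2)` with the given mean and SD:
#' `shape1 = mean * (mean (1 - mean) / sd^2 - 1)`, `shape2` analogous.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return Named vector `c(shape1, shape2)`.
#' @export
moment_match_beta <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1)
  if (sd <= 0) stop("sd must be positive")
  if (sd^2 >= mean * (1 - mean))
    stop("variance too large for a beta distribution with this mean")
  k <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Moment-matched lognormal distribution
#'
#' Solves for `(meanlog, sdlog)` with the given mean and SD:
#' `sdlog^2 = log(1 + sd^2/mean^2)`, `meanlog = log(mean) - sdlog^2/2`.
#'
#' @param mean Mean (> 0).
#' @param sd Standard deviation (> 0).
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
moment_match_lognormal <- function(mean, sd) {
  stopifnot(mean > 0)
  if (sd <= 0) stop("sd must be positive")
  s2 <- log(1 + sd^2 / mean^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
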