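#' Net monetary benefit
#'
#' `NB = wtp * qaly - cost`, per draw and strategy.
#'
#' @param cost,qaly Numeric vectors (or scalars) of discounted cost and
#'   QALYs.
#' @param wtp Willingness-to-pay threshold ($/QALY, >= 0).
#' @return Net benefit in dollars.
#' @export
net_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * qaly - cost
}

#' Per-patient expected value of perfect information
#'
#' For each willingness-to-pay threshold,
#' `EVPI = E[max over strategies of NB] - max over strategies of E[NB]`,
#' the expected foregone net benefit of deciding under current rather than
#' perfect information.
#'
#' @param psa A [run_psa()] result, or any data frame with per-draw
#'   `cost_screen`, `qaly_screen`, `cost_none`, `qaly_none`.
#' @param wtp_grid Willingness-to-pay thresholds ($/QALY).
#' @return Object of class `crc_evpi`: data frame with columns `wtp`,
#'   `evpi`.
#' @export
evpi_curve <- function(psa, wtp_grid = seq(0, 150000, by = 1000)) {
  need <- c("cost_screen", "qaly_screen", "cost_none", "qaly_none")
  if (!all(need %in% names(psa))) stop("psa lacks per-strategy outcomes")
  if (nrow(psa) == 0) stop("empty PSA sample")
  evpi <- vapply(wtp_grid, function(l) {
    nb <- cbind(net_benefit(psa$cost_screen, psa$qaly_screen, l),
                net_benefit(psa$cost_none, psa$qaly_none, l))
    mean(pmax(nb[, 1], nb[, 2])) - max(colMeans(nb))
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, evpi = evpi),
            class = c("crc_evpi", "data.frame"))
}
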