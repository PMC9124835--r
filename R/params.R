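#' Health states of the natural-history model
#'
#' The model follows the adenoma-carcinoma sequence through nine states:
#' normal mucosa, small (<1 cm) and large (>=1 cm) adenoma, preclinical
#' (asymptomatic, undiagnosed) early- and late-stage colorectal cancer (CRC),
#' clinically detected early- and late-stage CRC, CRC death and death from
#' other causes. The two death states are absorbing. All matrices and state
#' vectors in the package use this ordering.
#'
#' @format Character vector of length 9.
#' @export
crc_states <- c(
  "normal", "small_adenoma", "large_adenoma",
  "preclin_early_crc", "preclin_late_crc",
  "clin_early_crc", "clin_late_crc",
  "crc_death", "other_death"
)

# index helpers (internal); state ordering is load-bearing everywhere
.S <- as.list(seq_along(crc_states))
names(.S) <- crc_states
.ALIVE    <- 1:7
.ADENOMA  <- 2:3
.PRECLIN  <- 4:5
.CLIN     <- 6:7
.AT_RISK  <- 1:5  # alive without clinical CRC
.DEAD     <- 8:9

#' Calibrated natural-history parameters
#'
#' Constructs and validates the vector of the nine unknown parameters of the
#' natural-history model. Defaults are the generating ("true") values used
#' to simulate the synthetic calibration targets.
#'
#' @param padeno Adenoma prevalence at age 50 (proportion).
#' @param psmall Proportion of prevalent adenomas at age 50 that are small.
#' @param l Scale of the Weibull hazard for adenoma onset.
#' @param gamma Shape of the Weibull hazard for adenoma onset.
#' @param lambda2 Annual rate, small -> large adenoma.
#' @param lambda3 Annual rate, large adenoma -> preclinical early CRC.
#' @param lambda4 Annual rate, preclinical early -> preclinical late CRC.
#' @param lambda5 Annual rate, preclinical early -> clinical early CRC.
#' @param lambda6 Annual rate, preclinical late -> clinical late CRC.
#' @return Named numeric vector of class `crc_params`.
#' @examples
#' crc_params()                       # true values
#' crc_params(padeno = 0.3)           # vary one parameter
#' @export
crc_params <- function(padeno = 0.25, psmall = 0.71,
                       l = 2.86e-06, gamma = 2.78,
                       lambda2 = 0.0346, lambda3 = 0.0215,
                       lambda4 = 0.3697, lambda5 = 0.2382,
                       lambda6 = 0.4582) {
  theta <- c(padeno = padeno, psmall = psmall, l = l, gamma = gamma,
             lambda2 = lambda2, lambda3 = lambda3, lambda4 = lambda4,
             lambda5 = lambda5, lambda6 = lambda6)
  validate_crc_params(theta)
  class(theta) <- "crc_params"
  theta
}

#' @rdname crc_params
#' @param theta Named numeric vector with the nine parameter names.
#' @export
validate_crc_params <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 9L)
  nm <- c("padeno", "psmall", "l", "gamma",
          "lambda2", "lambda3", "lambda4", "lambda5", "lambda6")
  if (!all(nm %in% names(theta)))
    stop("crc_params must be named: ", paste(nm, collapse = ", "))
  theta <- theta[nm]
  if (!all(is.finite(theta))) stop("non-finite parameter value")
  if (theta["padeno"] <= 0 || theta["padeno"] >= 1)
    stop("padeno must be in (0, 1)")
  if (theta["psmall"] <= 0 || theta["psmall"] >= 1)
    stop("psmall must be in (0, 1)")
  if (any(theta[3:9] <= 0))
    stop("l, gamma and all transition rates must be > 0")
  invisible(theta)
}

#' Fixed (external) natural-history parameters
#'
#' The two cancer-specific annual mortality rates are treated as known
#' (obtainable from cancer registries) and the age-50 preclinical CRC
#' prevalences are fixed inputs to the initial cohort distribution.
#'
#' @param lambda7 Annual CRC mortality rate from clinical early-stage disease.
#' @param lambda8 Annual CRC mortality rate from clinical late-stage disease.
#' @param p_preclin_early_50 Prevalence of preclinical early CRC at age 50.
#' @param p_preclin_late_50 Prevalence of preclinical late CRC at age 50.
#' @return Named numeric vector of class `crc_fixed_params`.
#' @export
crc_fixed_params <- function(lambda7 = 0.0302, lambda8 = 0.2099,
                             p_preclin_early_50 = 0.0012,
                             p_preclin_late_50 = 0.0008) {
  stopifnot(lambda7 > 0, lambda8 > 0,
            p_preclin_early_50 >= 0, p_preclin_early_50 < 1,
            p_preclin_late_50 >= 0, p_preclin_late_50 < 1,
            p_preclin_early_50 + p_preclin_late_50 < 1)
  out <- c(lambda7 = lambda7, lambda8 = lambda8,
           p_preclin_early_50 = p_preclin_early_50,
           p_preclin_late_50 = p_preclin_late_50)
  class(out) <- "crc_fixed_params"
  out
}
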