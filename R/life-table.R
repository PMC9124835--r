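#' Background all-cause mortality life table
#'
#' Builds the age -> annual other-cause mortality rate table used by the
#' natural-history model. The default is a synthetic Gompertz-Makeham
#' schedule, \eqn{\mu(a) = A + B e^{k a}}, with parameters chosen so that
#' the remaining life expectancy at age 50 (about 33 years) is plausible
#' for the cohort the model simulates (US women, 2014 era). The fixture is
#' synthetic: it stands in for a published life table, not copied from one.
#'
#' @param A Age-independent (Makeham) mortality component, per year.
#' @param B Level of the senescent (Gompertz) component.
#' @param k Slope of the senescent component, per year of age.
#' @param ages Integer ages covered (default 0-100).
#' @return Object of class `crc_life_table`: data frame with columns
#'   `age` and `mortality_rate`.
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt, from = 50)
#' @export
make_life_table <- function(A = 9e-04, B = 6e-06, k = 0.112,
                            ages = 0:100) {
  stopifnot(A >= 0, B >= 0, k >= 0)
  rate <- A + B * exp(k * ages)
  new_life_table(data.frame(age = as.integer(ages), mortality_rate = rate))
}

new_life_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("age", "mortality_rate") %in% names(df)))
  if (any(df$mortality_rate < 0)) stop("negative mortality rate")
  if (anyDuplicated(df$age)) stop("duplicated ages in life table")
  df <- df[order(df$age), c("age", "mortality_rate")]
  rownames(df) <- NULL
  class(df) <- c("crc_life_table", "data.frame")
  df
}

# rate lookup for integer ages; errors on gaps
life_table_rate <- function(lt, ages) {
  i <- match(ages, lt$age)
  if (anyNA(i))
    stop("life table does not cover ages: ",
         paste(ages[is.na(i)], collapse = ", "))
  lt$mortality_rate[i]
}

#' @describeIn make_life_table Remaining (curtate-style) life expectancy at
#'   `from`, integrating exp(-cumulative hazard) over annual steps; a
#'   plausibility check on fixtures.
#' @param lt A `crc_life_table`.
#' @param from Starting age.
#' @export
life_expectancy <- function(lt, from = 50) {
  sel <- lt$age >= from
  mu <- lt$mortality_rate[sel]
  surv <- exp(-cumsum(mu))
  # trapezoid on annual survival curve starting at S=1
  sum((c(1, surv[-length(surv)]) + surv) / 2)
}

#' Read / write a life table as CSV
#'
#' Plain CSV with header `age,mortality_rate`. If a column `qx` of annual
#' death probabilities is supplied instead of rates, it is converted with
#' `rate = -log(1 - qx)`.
#'
#' @param path File path.
#' @return [read_life_table()] returns a `crc_life_table`;
#'   [write_life_table()] returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.csv(path)
  if (!"mortality_rate" %in% names(df) && "qx" %in% names(df))
    df$mortality_rate <- -log(1 - df$qx)
  new_life_table(df[, c("age", "mortality_rate")])
}

#' @rdname read_life_table
#' @param lt A `crc_life_table`.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}
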