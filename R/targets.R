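#' Generate synthetic calibration targets
#'
#' Runs the microsimulation at a known ("true") parameter set and turns the
#' replicated outputs into age-specific calibration targets with
#' replication-based uncertainty. Four target types are produced: adenoma
#' prevalence and proportion of small adenomas (cohorts of `n_adenoma`
#' individuals) and clinical CRC incidence per 100,000 person-years for
#' early and late stage (cohorts of `n_cancer`). Each replication simulates
#' one cohort of the stated size; the target mean is the average over
#' replications and the standard error is the standard deviation across
#' replications — the sampling error of one observed study of that size,
#' which is what the calibration likelihood needs.
#'
#' Defaults reproduce the generating conditions of the study design:
#' 100 replications, adenoma cohorts of 500, incidence cohorts of 100,000.
#'
#' @inheritParams cohort_trace
#' @param n_reps Number of replications (>= 2).
#' @param n_adenoma Cohort size for the adenoma-related targets.
#' @param n_cancer Cohort size for the incidence targets.
#' @param bins A [crc_age_bins()] scheme.
#' @param seed Integer seed; the full target set is reproducible from it.
#' @return Object of class `crc_targets`: data frame with columns
#'   `target_type`, `age_lo`, `age_hi`, `mean`, `se`, `n`. A floor of 1e-6
#'   is applied to degenerate zero-variance standard errors; bins undefined
#'   in every replication are dropped with a warning.
#' @export
generate_targets <- function(theta_u = crc_params(),
                             theta_k = crc_fixed_params(),
                             lt = make_life_table(),
                             n_reps = 100, n_adenoma = 500,
                             n_cancer = 100000,
                             bins = crc_age_bins(), seed = 1) {
  stopifnot(n_reps >= 2)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_reps)
  sim_one <- function(nc, s) {
    p <- simulate_individuals(theta_u, theta_k, lt, nc, seed = s)
    aggregate_outputs(p, bins)
  }
  aden <- lapply(seq_len(n_reps),
                 function(r) sim_one(n_adenoma, rep_seeds[r]))
  canc <- lapply(seq_len(n_reps),
                 function(r) sim_one(n_cancer, rep_seeds[n_reps + r]))
  template <- aden[[1]][, c("target_type", "age_lo", "age_hi")]
  is_aden <- template$target_type %in% c("adenoma_prev", "prop_small")
  vals <- sapply(seq_len(n_reps), function(r)
    ifelse(is_aden, aden[[r]]$value, canc[[r]]$value))
  m <- apply(vals, 1, mean, na.rm = TRUE)
  s <- apply(vals, 1, stats::sd, na.rm = TRUE)
  dropped <- !is.finite(m)
  if (any(dropped))
    warning("dropping target cells undefined in every replication: ",
            paste(template$target_type[dropped], template$age_lo[dropped],
                  collapse = "; "))
  out <- cbind(template, mean = m, se = pmax(s, 1e-6),
               n = ifelse(is_aden, n_adenoma, n_cancer))
  out <- out[!dropped, ]
  rownames(out) <- NULL
  structure(out, class = c("crc_targets", "data.frame"),
            bins = bins, seed = seed, n_reps = n_reps)
}

#' Read / write a target set as CSV
#'
#' Header `target_type,age_lo,age_hi,mean,se,n`.
#'
#' @param targets A `crc_targets` data frame.
#' @param path File path.
#' @export
write_targets <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path)
  need <- c("target_type", "age_lo", "age_hi", "mean", "se", "n")
  if (!all(need %in% names(df))) stop("malformed target CSV: ", path)
  if (any(df$se <= 0)) stop("target standard errors must be positive")
  structure(df[, need], class = c("crc_targets", "data.frame"),
            bins = bins_from_targets(df))
}

# reconstruct the bin scheme implied by a target table
bins_from_targets <- function(df) {
  prev <- sort(unique(df$age_lo[df$target_type == "adenoma_prev"]))
  inc <- df[df$target_type == "inc_early", ]
  inc <- inc[order(inc$age_lo), ]
  w <- if (nrow(inc)) unique(inc$age_hi - inc$age_lo + 1) else 5
  crc_age_bins(prev_ages = prev, inc_lo = inc$age_lo, inc_width = w[1])
}
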