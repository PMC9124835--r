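#' Pipeline configuration
#'
#' Bundles every stage parameter of the analysis pipeline, resolved from a
#' profile: `"desk"` (laptop-scale: reduced replications, ESS target and
#' PSA size) or `"full"` (the generating study scale: 100 replications,
#' ESS target 5000, 5000-draw PSA on 100,000-person cohorts). All
#' paper-derived constants live here or in [crc_params()] /
#' [cea_params()] defaults, so alternative scenarios are plain
#' configuration edits.
#'
#' @param profile `"desk"` or `"full"`.
#' @param seed Base seed; per-stage seeds are derived deterministically.
#' @param out_dir Artifact directory.
#' @param ... Named overrides of individual preset entries.
#' @return List of class `crc_config`.
#' @export
crc_config <- function(profile = c("desk", "full"), seed = 1,
                       out_dir = "crcuq-artifacts", ...) {
  profile <- match.arg(profile)
  preset <- if (profile == "desk") {
    list(n_reps = 30, n_adenoma = 500, n_cancer = 100000,
         imis = imis_control_desk(), n_validate = 300,
         n_psa = 250, n_micro = 2000,
         wtp_grid = seq(0, 150000, by = 1000))
  } else {
    list(n_reps = 100, n_adenoma = 500, n_cancer = 100000,
         imis = imis_control(), n_validate = 5000,
         n_psa = 5000, n_micro = 100000,
         wtp_grid = seq(0, 150000, by = 1000))
  }
  over <- list(...)
  preset[names(over)] <- over
  structure(c(list(profile = profile, seed = seed, out_dir = out_dir),
              preset),
            class = "crc_config")
}

stage_order <- c("targets", "calibrate", "validate", "cea", "psa", "evpi")

stage_deps <- list(targets = character(), calibrate = "targets",
                   validate = "calibrate", cea = "calibrate",
                   psa = "calibrate", evpi = "psa")

stage_file <- function(config, stage, name)
  file.path(config$out_dir, paste0(stage, "-", name))

stage_done <- function(config, stage)
  file.exists(file.path(config$out_dir, paste0(stage, ".yaml")))

write_sidecar <- function(config, stage, extra = list()) {
  side <- c(list(stage = stage, profile = config$profile,
                 seed = config$seed,
                 config_hash = config_hash(config),
                 package_version = as.character(
                   utils::packageVersion("crcuq"))),
            extra)
  yaml::write_yaml(side, file.path(config$out_dir, paste0(stage, ".yaml")))
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small rolling hash; stable across sessions, no extra dependency
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Run one pipeline stage
#'
#' Stages: `targets` (synthetic calibration targets), `calibrate` (IMIS
#' posterior), `validate` (posterior-predictive check), `cea`
#' (deterministic incremental outcomes at the MAP and mean external
#' values), `psa` (all four uncertainty characterizations), `evpi` (EVPI
#' curves per approach). Each stage writes CSV artifacts plus a YAML
#' sidecar recording profile, seed and a config hash; re-running an
#' unchanged configuration rewrites identical artifacts. A stage whose
#' upstream artifacts are missing stops with an error naming the missing
#' stage.
#'
#' @param stage Stage name.
#' @param config A [crc_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config = crc_config()) {
  stage <- match.arg(stage, stage_order)
  for (dep in stage_deps[[stage]])
    if (!stage_done(config, dep))
      stop("stage '", stage, "' requires stage '", dep,
           "' to have run first")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lt <- make_life_table()
  paths <- switch(stage,
    targets = {
      tg <- generate_targets(crc_params(), crc_fixed_params(), lt,
                             n_reps = config$n_reps,
                             n_adenoma = config$n_adenoma,
                             n_cancer = config$n_cancer,
                             seed = config$seed)
      write_targets(tg, stage_file(config, "targets", "set.csv"))
    },
    calibrate = {
      tg <- read_targets(stage_file(config, "targets", "set.csv"))
      fit <- crc_calibrate(tg, control = config$imis,
                           seed = config$seed + 1L)
      s <- posterior_summary(fit)
      draws <- cbind(as.data.frame(fit$posterior$resample),
                     log_post = (fit$posterior$log_prior +
                                   fit$posterior$log_lik)[
                                     fit$posterior$resample_idx])
      p1 <- stage_file(config, "calibrate", "draws.csv")
      utils::write.csv(draws, p1, row.names = FALSE)
      p2 <- stage_file(config, "calibrate", "summary.csv")
      utils::write.csv(s$table, p2, row.names = FALSE)
      p3 <- stage_file(config, "calibrate", "correlation.csv")
      utils::write.csv(as.data.frame(s$correlation), p3, row.names = FALSE)
      c(p1, p2, p3)
    },
    validate = {
      fit <- reload_calibration(config)
      pp <- posterior_predictive(fit, n_draws = config$n_validate,
                                 seed = config$seed + 2L)
      p <- stage_file(config, "validate", "posterior-predictive.csv")
      utils::write.csv(pp, p, row.names = FALSE)
      p
    },
    cea = {
      fit <- reload_calibration(config)
      r_s <- simulate_strategy(fit$map, fit$theta_k, lt, cea_params(),
                               "colonoscopy_q10", n = config$n_micro,
                               seed = config$seed + 3L)
      r_n <- simulate_strategy(fit$map, fit$theta_k, lt, cea_params(),
                               "no_screening", n = config$n_micro,
                               seed = config$seed + 3L)
      inc <- incremental_outcomes(r_s, r_n)
      p <- stage_file(config, "cea", "map-point.csv")
      utils::write.csv(data.frame(strategy = c("colonoscopy_q10",
                                               "no_screening"),
                                  cost = c(r_s$cost, r_n$cost),
                                  qaly = c(r_s$qaly, r_n$qaly),
                                  delta_cost = c(inc$delta_cost, NA),
                                  delta_qaly = c(inc$delta_qaly, NA)),
                       p, row.names = FALSE)
      p
    },
    psa = {
      fit <- reload_calibration(config)
      ext <- fit_external_distributions()
      ps <- lapply(uq_approaches, function(ap) {
        x <- run_psa(ap, fit, ext, n_psa = config$n_psa,
                     n_micro = config$n_micro,
                     seed = config$seed + 4L)
        cbind(approach = ap, as.data.frame(x))
      })
      p <- stage_file(config, "psa", "draws.csv")
      utils::write.csv(do.call(rbind, ps), p, row.names = FALSE)
      p
    },
    evpi = {
      ps <- utils::read.csv(stage_file(config, "psa", "draws.csv"))
      curves <- lapply(uq_approaches, function(ap)
        evpi_curve(ps[ps$approach == ap, ], config$wtp_grid)$evpi)
      names(curves) <- c("evpi_a1", "evpi_a2", "evpi_a3", "evpi_a4")
      p <- stage_file(config, "evpi", "curves.csv")
      utils::write.csv(cbind(data.frame(wtp = config$wtp_grid),
                             as.data.frame(curves)),
                       p, row.names = FALSE)
      p
    })
  write_sidecar(config, stage)
  invisible(paths)
}

# rebuild a minimal crc_calib from stage artifacts (draws + targets)
reload_calibration <- function(config) {
  tg <- read_targets(stage_file(config, "targets", "set.csv"))
  draws <- utils::read.csv(stage_file(config, "calibrate", "draws.csv"))
  lp <- draws$log_post
  rs <- as.matrix(draws[, setdiff(names(draws), "log_post")])
  post <- structure(list(draws = rs, log_prior = lp * 0, log_lik = lp,
                         weights = rep(1 / nrow(rs), nrow(rs)),
                         resample = rs,
                         resample_idx = seq_len(nrow(rs)),
                         ess = NA_real_, n_unique = nrow(unique(rs)),
                         iterations = NA_integer_),
                    class = "crc_posterior")
  structure(list(posterior = post, targets = tg,
                 theta_k = crc_fixed_params(), lt = make_life_table(),
                 priors = crc_priors(), seed = config$seed,
                 map = stats::setNames(as.numeric(rs[which.max(lp), ]),
                                       colnames(rs))),
            class = "crc_calib")
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order on one configuration.
#'
#' @param config A [crc_config()].
#' @return Invisibly, the artifact directory.
#' @export
run_pipeline <- function(config = crc_config()) {
  for (st in stage_order) run_stage(st, config)
  invisible(config$out_dir)
}
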