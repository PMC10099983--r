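#' Read a workflow configuration file
#'
#' YAML or JSON file holding input paths, MCMC settings, prior overrides,
#' LTRE options and the output directory. Missing entries take defaults.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- list(out_dir = "nestipm_out", seed = 1, profile = "test",
                   scenario = "baseline", ltre_design = "random")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  structure(cfg, class = c("run_config", "list"))
}

.cfg_fit_config <- function(cfg) {
  fit_config(n_chains = cfg$n_chains, n_iter = cfg$n_iter,
             n_burnin = cfg$n_burnin, thin = cfg$thin,
             seed = cfg$seed, profile = cfg$profile)
}

.cfg_data <- function(cfg) {
  for (f in c("nests", "captures", "weather")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop_validation("input file for '", f, "' missing or not found")
    }
  }
  nests <- read_nest_table(cfg$nests)
  weather <- read_weather_table(cfg$weather)
  years <- if (!is.null(cfg$years)) seq(cfg$years[1], cfg$years[2])
           else seq(min(nests$year), max(nests$year))
  captures <- read_capture_table(cfg$captures, years)
  donor <- NULL
  if (!is.null(cfg$window_donor_nests)) {
    donor <- compute_windows(read_nest_table(cfg$window_donor_nests), years)
  }
  ipm_data(nests, captures, weather, years, donor_windows = donor)
}

#' Simulate a dataset bundle to disk
#'
#' @param config A `run_config` (or path to one).
#' @param scenario Scenario name ([planted_scenarios()]); overrides config.
#' @param seed Seed; overrides config.
#' @return Output directory path, invisibly.
#' @export
run_simulate <- function(config, scenario = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  scenario <- scenario %||% cfg$scenario
  seed <- seed %||% cfg$seed
  truth <- planted_scenarios(scenario)
  sim <- simulate_dataset(truth, seed = seed)
  dir <- file.path(cfg$out_dir, "data")
  write_simulation(sim, dir)
  message(sprintf("simulated %d nests, %d capture histories over %d years -> %s",
                  nrow(sim$nests), length(unique(sim$captures$individual)),
                  length(sim$years), dir))
  invisible(dir)
}

#' Fit the IPM per the configuration and archive the posterior
#'
#' Writes per-chain CSV draws, a JSON manifest, a summary CSV (parameter,
#' median, lower95, upper95) and a diagnostics report (R-hat table, flagged
#' chains, posterior predictive table).
#'
#' @param config A `run_config` or path.
#' @return The `ipm_fit`, invisibly.
#' @export
run_fit <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  data <- .cfg_data(cfg)
  priors <- do.call(default_priors, cfg$priors %||% list())
  fit <- fit_ipm(data, .cfg_fit_config(cfg), priors)
  dir <- file.path(cfg$out_dir, "posterior")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(fit$chains)) {
    utils::write.csv(as.data.frame(fit$chains[[ch]]),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(parameters = fit$manifest, years = fit$years,
         components = fit$components, flagged_chains = fit$flagged_chains,
         config = unclass(fit$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  summ <- .summarize_draws(fit, exclude_flagged = TRUE)
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  rhat_tab <- data.frame(parameter = names(fit$rhat), rhat = fit$rhat,
                         row.names = NULL)
  utils::write.csv(rhat_tab, file.path(dir, "rhat.csv"), row.names = FALSE)
  ppt <- posterior_predictive_table(fit, seed = cfg$seed)
  utils::write.csv(ppt$table, file.path(dir, "posterior_predictive.csv"),
                   row.names = FALSE)
  message(sprintf("posterior archive written to %s (coverage %.2f)", dir,
                  ppt$coverage))
  invisible(fit)
}

.load_fit_archive <- function(cfg) {
  dir <- file.path(cfg$out_dir, "posterior")
  if (!dir.exists(dir)) {
    stop_validation("posterior archive not found at ", dir,
                    "; run the fit step first")
  }
  # archives are only reloaded for LTRE/projection; refit data bundle too
  chains <- lapply(sort(list.files(dir, pattern = "^chain\\d+\\.csv$",
                                   full.names = TRUE)), function(f) {
    m <- as.matrix(utils::read.csv(f, check.names = FALSE))
    m
  })
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  data <- .cfg_data(cfg)
  fit <- structure(list(chains = chains,
                        manifest = man$parameters, data = data,
                        config = man$config, priors = NULL,
                        components = man$components,
                        years = man$years,
                        flagged_chains = man$flagged_chains %||% integer(),
                        miss_idx = NULL),
                   class = "ipm_fit")
  fit$rhat <- gelman_rubin(chains)
  fit$summary <- .summarize_draws(fit)
  fit
}

#' Run a posterior transient LTRE from an archived fit
#'
#' @param config A `run_config` or path.
#' @param design `"random"`, `"fixed"` or `"period"` (overrides config).
#' @param fit Optionally, an in-memory `ipm_fit` (skips the archive).
#' @return The `posterior_ltre`, invisibly.
#' @export
run_ltre <- function(config, design = NULL, fit = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  design <- design %||% cfg$ltre_design
  if (identical(design, "period")) {
    p1 <- cfg$period1; p2 <- cfg$period2
    if (is.null(p1) || is.null(p2) || length(seq(p1[1], p1[2])) !=
        length(seq(p2[1], p2[2]))) {
      stop_validation("period design needs equal-length period1/period2 in config")
    }
    p1 <- seq(p1[1], p1[2]); p2 <- seq(p2[1], p2[2])
  } else p1 <- p2 <- NULL
  if (is.null(fit)) fit <- .load_fit_archive(cfg)
  res <- posterior_ltre(fit, design, period1 = p1, period2 = p2,
                        n_draws = cfg$ltre_draws %||% 500,
                        exclude_flagged = TRUE)
  dir <- file.path(cfg$out_dir, "ltre")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(seq_len(nrow(res$draws)), function(k)
    data.frame(draw = k, design = design,
               parameter = colnames(res$draws),
               group = unname(LTRE_GROUPS[colnames(res$draws)]),
               value = res$draws[k, ], row.names = NULL)))
  utils::write.csv(long, file.path(dir,
                                   sprintf("contributions_%s.csv", design)),
                   row.names = FALSE)
  utils::write.csv(res$group_summary,
                   file.path(dir, sprintf("groups_%s.csv", design)),
                   row.names = FALSE)
  message("LTRE results written to ", dir)
  invisible(res)
}

#' Stochastic forward projection from an archived fit
#'
#' @param config A `run_config` or path.
#' @param horizon Projection horizon in years.
#' @param fit Optionally an in-memory `ipm_fit`.
#' @return The quantile table, invisibly.
#' @export
run_project <- function(config, horizon = NULL, fit = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  horizon <- horizon %||% cfg$horizon %||% 10
  if (is.null(fit)) fit <- .load_fit_archive(cfg)
  tab <- forward_projection_check(fit, horizon = horizon,
                                  reps = cfg$projection_reps %||% 1000,
                                  seed = cfg$seed, exclude_flagged = TRUE)
  dir <- file.path(cfg$out_dir, "projection")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab, file.path(dir, "projection.csv"), row.names = FALSE)
  message("projection written to ", dir)
  invisible(tab)
}
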