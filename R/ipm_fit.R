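#' Assemble the three observation streams into a model-ready bundle
#'
#' Combines validated nest records, capture histories and daily weather into
#' the object [fit_ipm()] consumes: population-level count series, m-arrays,
#' individual-level reproduction records of known-age mothers, standardized
#' environmental covariates, and identification probabilities.
#'
#' @param nests Nest data frame ([read_nest_table()]).
#' @param captures A `capture_histories` object.
#' @param weather Daily weather data frame ([read_weather_table()]).
#' @param years Study years (consecutive integers).
#' @param donor_windows Optional [compute_windows()] result from a donor
#'   population for years without local phenology.
#' @return An object of class `ipm_data`.
#' @export
ipm_data <- function(nests, captures, weather, years, donor_windows = NULL) {
  years <- sort(years)
  if (any(diff(years) != 1)) stop_validation("years must be consecutive")
  T <- length(years)
  if (T < 5) stop_validation("need at least 5 study years")
  counts <- build_population_counts(nests, captures, years)
  windows <- compute_windows(nests, years)
  covariates <- build_covariates(weather, windows, years, donor_windows)
  marr <- build_marray(captures)
  known <- nests$female_age %in% AGE_CLASSES & nests$year %in% years
  repro <- data.frame(age = nests$female_age[known],
                      year = match(nests$year[known], years),
                      clutch = nests$clutch[known],
                      fledged = nests$fledged[known])
  structure(list(years = years, T = T, counts = counts,
                 covariates = covariates, windows = windows, marr = marr,
                 repro = repro, nests = nests, captures = captures),
            class = "ipm_data")
}

# sufficient statistics and data list for the C++ sampler
.sampler_data <- function(data, priors, components) {
  T <- data$T
  rp <- data$repro
  a <- .age_index(rp$age)
  tab <- function(vals, subset) {
    M <- matrix(0, 2, T)
    if (any(subset)) {
      agg <- aggregate(vals[subset],
                       list(a = a[subset], t = rp$year[subset]), sum)
      M[cbind(agg$a, agg$t)] <- agg$x
    }
    M
  }
  all <- rep(TRUE, nrow(rp))
  succ <- rp$fledged > 0
  zero <- !succ
  nf_zero <- if (any(zero)) {
    agg <- aggregate(rep(1, sum(zero)),
                     list(a = a[zero], t = rp$year[zero],
                          clutch = rp$clutch[zero]), sum)
    as.matrix(cbind(agg$a - 1L, agg$t - 1L, agg$clutch, agg$x))
  } else matrix(0L, 0, 4)
  storage.mode(nf_zero) <- "integer"
  pCapB <- data$counts$pCapB
  pCapB[is.na(pCapB)] <- mean(pCapB, na.rm = TRUE)  # zero-nest years
  miss <- attr(data$covariates, "missing")
  cv <- data$covariates
  missIdx <- which(miss, arr.ind = TRUE)
  missIdx <- cbind(as.integer(missIdx[, 2]) - 1L,
                   as.integer(missIdx[, 1]) - 1L)
  storage.mode(missIdx) <- "integer"
  zero_fill <- function(x) { x[is.na(x)] <- 0; x }
  list(T = T,
       marrJ = data$marr$juv, marrA = data$marr$ad,
       clutch_n = tab(rep(1, nrow(rp)), all),
       clutch_sum = tab(rp$clutch, all),
       clutch_lfact = tab(lfactorial(rp$clutch), all),
       nf_nsucc = tab(rep(1, nrow(rp)), succ),
       nf_sumf = tab(rp$fledged, succ),
       nf_sumcf = tab(rp$clutch - rp$fledged, succ),
       nf_lchoose = tab(lchoose(rp$clutch, rp$fledged), succ),
       nf_zero = nf_zero,
       fc = as.integer(data$counts$first_clutches),
       eggs = as.integer(data$counts$eggs),
       fl = as.integer(data$counts$fledglings),
       nr = as.integer(data$counts$newly_ringed),
       pCapB = pCapB,
       rainPH = zero_fill(cv$rain_ph), tempPH = zero_fill(cv$temp_ph),
       rainPF = zero_fill(cv$rain_pf),
       missIdx = missIdx,
       flags = c("cjs", "clutch", "nestfate", "counts", "state") %in%
         components,
       prior_bounds = c(priors$omega_max, priors$N1_max, priors$sigma_max,
                        priors$beta_bound, priors$cs_max))
}

#' Prior bounds for the IPM
#'
#' Noninformative priors with biologically sensible upper bounds:
#' probabilities (and the immigrant age-mixing proportion) are Uniform(0,1);
#' mean clutch size Uniform(0, `cs_max`]; covariate slopes
#' Uniform(-`beta_bound`, `beta_bound`) on the link scale; year-effect SDs
#' Uniform(0, `sigma_max`); annual expected immigrant totals Uniform(0,
#' `omega_max`), defaulting to twice the largest observed newly-ringed count
#' plus 10 when fitted to data.
#'
#' @param ... Named overrides of `cs_max`, `beta_bound`, `sigma_max`,
#'   `omega_max`, `N1_max`.
#' @return A named list of bounds (class `ipm_priors`).
#' @export
default_priors <- function(...) {
  pr <- list(cs_max = 12, beta_bound = 5, sigma_max = 3,
             omega_max = NA_real_, N1_max = NA_real_)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(pr))
  if (length(unknown)) {
    stop_validation("unknown prior bound(s): ", paste(unknown, collapse = ", "))
  }
  pr[names(ov)] <- ov
  for (b in c("cs_max", "beta_bound", "sigma_max")) {
    if (!is.na(pr[[b]]) && pr[[b]] <= 0) {
      stop_validation("prior bound '", b, "' must be positive")
    }
  }
  structure(pr, class = "ipm_priors")
}

.resolve_priors <- function(priors, data) {
  if (is.na(priors$omega_max)) {
    priors$omega_max <- 2 * max(data$counts$newly_ringed, 1) + 10
  }
  if (is.na(priors$N1_max)) {
    priors$N1_max <- 5 * max(data$counts$first_clutches, 1) + 50
  }
  priors
}

#' Draw top-level parameters from the prior
#'
#' @param priors An `ipm_priors` object (bounds must be resolved, i.e. no
#'   `NA`; pass `omega_max`/`N1_max` explicitly if not fitted to data).
#' @param n Number of draws.
#' @return Data frame of prior draws for the top-level parameters.
#' @export
prior_predictive <- function(priors, n = 1000) {
  if (is.na(priors$omega_max)) priors$omega_max <- 50
  probs <- c("pB_Y", "pB_A", "pNS", "sN_Y", "sN_A", "sJ", "sA")
  out <- as.data.frame(c(
    setNames(lapply(probs, function(p) runif(n)), probs),
    list(CS_Y = runif(n, 0, priors$cs_max), CS_A = runif(n, 0, priors$cs_max),
         q_imm = runif(n)),
    setNames(lapply(1:5, function(i)
      runif(n, -priors$beta_bound, priors$beta_bound)),
      c("beta_rain_pNS", "beta_temp_pNS", "beta_rain_sN", "beta_temp_sN",
        "beta_rain_sJ")),
    setNames(lapply(1:6, function(i) runif(n, 0, priors$sigma_max)),
             paste0("sigma_", c("pB", "CS", "pNS", "sN", "sJ", "sA")))))
  out
}

#' MCMC configuration
#'
#' The default profile mirrors a full analysis (4 chains of 200,000
#' iterations, 50,000 burn-in, thinning 30); the `"test"` profile (3 chains
#' of 20,000, 5,000 burn-in, thinning 10) is sized for simulation studies
#' and test suites.
#'
#' @param n_chains,n_iter,n_burnin,thin MCMC dimensions.
#' @param seed Base seed; chain c uses `seed + c`.
#' @param profile `"full"` or `"test"`; explicit arguments override.
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_chains = NULL, n_iter = NULL, n_burnin = NULL,
                       thin = NULL, seed = 1, profile = c("full", "test")) {
  profile <- match.arg(profile)
  def <- if (profile == "full") list(4L, 2e5, 5e4, 30L)
         else list(3L, 2e4, 5e3, 10L)
  cfg <- list(n_chains = n_chains %||% def[[1]], n_iter = n_iter %||% def[[2]],
              n_burnin = n_burnin %||% def[[3]], thin = thin %||% def[[4]],
              seed = seed, profile = profile)
  if (cfg$n_burnin >= cfg$n_iter) stop_validation("n_burnin must be < n_iter")
  if (cfg$thin < 1) stop_validation("thin must be >= 1")
  structure(cfg, class = "fit_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.param_names <- function(T, nmiss_names = character()) {
  rates <- c("pB", "CS", "pNS", "sN", "sJ", "sA")
  c("pB_Y", "pB_A", "CS_Y", "CS_A", "pNS", "sN_Y", "sN_A", "sJ", "sA",
    "beta_rain_pNS", "beta_temp_pNS", "beta_rain_sN", "beta_temp_sN",
    "beta_rain_sJ", paste0("sigma_", rates), "q_imm",
    unlist(lapply(rates, function(r) sprintf("eps_%s[%d]", r, 1:T))),
    sprintf("Omega_tot[%d]", 2:T),
    "N_Y[1]", "N_A[1]",
    as.vector(t(outer(2:T, c("localY", "ImmY", "survA", "ImmA"),
                      function(t, k) sprintf("%s[%d]", k, t)))),
    nmiss_names)
}

.top_level_params <- function() .param_names(1)[1:21]

.init_state <- function(sd_list, priors, chain_seed) {
  T <- sd_list$T
  repeat_ok <- FALSE
  for (try in 1:100) {
    set.seed(chain_seed + 7919 * (try - 1))
    mu <- c(runif(1, .5, .95), runif(1, .6, .95),  # pB
            runif(1, 5, 7), runif(1, 5.5, 7.5),    # CS
            runif(1, .6, .95), runif(1, .7, .95), runif(1, .75, .95),  # pNS sN
            runif(1, .05, .25), runif(1, .3, .6))  # sJ sA
    betas <- runif(5, -0.3, 0.3)
    sig <- runif(6, 0.05, 0.4)
    q <- runif(1, 0.1, 0.5)
    eps <- rnorm(6 * T, 0, 0.05)
    pcap <- sd_list$pCapB
    om <- pmax(sd_list$nr[-1] / pmax(pcap[-1], 0.05), 2) * runif(T - 1, .8, 1.4)
    om <- pmin(om, priors$omega_max * 0.9)
    Ntot_g <- pmax(sd_list$fc, 1) / (0.5 * (mu[1] + mu[2]))
    NYg <- pmax(round(0.35 * Ntot_g), 1)
    NAg <- pmax(round(0.65 * Ntot_g), 1)
    NYg[1] <- min(NYg[1], priors$N1_max)
    NAg[1] <- min(NAg[1], priors$N1_max)
    lat <- numeric(4 * (T - 1))
    for (t in 2:T) {
      k <- 4 * (t - 2)
      immY <- min(round(q * om[t - 1]), NYg[t])
      immA <- min(round((1 - q) * om[t - 1]), NAg[t])
      survA <- min(NAg[t] - immA, NYg[t - 1] + NAg[t - 1])
      lat[k + 1] <- NYg[t] - immY
      lat[k + 2] <- immY
      lat[k + 3] <- max(survA, 0)
      lat[k + 4] <- NAg[t] - lat[k + 3]
    }
    init <- c(mu, betas, sig, q, eps, om, NYg[1], NAg[1], lat,
              rnorm(nrow(sd_list$missIdx)))
    lp <- ipm_logpost_cpp(sd_list, init)$total
    if (is.finite(lp)) { repeat_ok <- TRUE; break }
  }
  if (!repeat_ok) stop_numeric("could not find finite initial state in 100 tries")
  init
}

.init_steps <- function(T, nmiss) {
  c(rep(0.05, 4), rep(0.03, 5),      # mu (CS on count scale gets same; adapts)
    rep(0.1, 5),                      # slopes
    rep(0.05, 6), 0.05,               # sigmas, q
    rep(0.2, 6 * T),                  # eps
    rep(2, T - 1),                    # Omega
    rep(4, 2), rep(3, 4 * (T - 1)),   # latents
    rep(0.3, nmiss))
}

#' Fit the integrated population model
#'
#' Joint Bayesian estimation of age-structured vital rates, immigration and
#' latent abundances by Metropolis-within-Gibbs sampling: adaptive Gaussian
#' random walks for continuous parameters (target acceptance about 0.44 per
#' scalar, adaptation frozen at the end of burn-in) and symmetric discrete
#' random walks for latent integer abundances. Initial values are simulated
#' until the posterior density is finite. Missing standardized covariates
#' are imputed as standard-normal latent draws. Each chain is seeded as
#' `seed + chain`, making runs fully reproducible.
#'
#' @param data An [ipm_data()] bundle.
#' @param config A [fit_config()].
#' @param priors A [default_priors()] object.
#' @param components Character vector of data components to include
#'   (default: all of `"cjs"`, `"clutch"`, `"nestfate"`, `"counts"`,
#'   `"state"`).
#' @return An object of class `ipm_fit` with per-chain draw matrices, a
#'   parameter manifest, convergence diagnostics and posterior summaries.
#' @seealso [fit_independent()], [gelman_rubin()], [posterior_ltre()]
#' @export
fit_ipm <- function(data, config = fit_config(profile = "test"),
                    priors = default_priors(),
                    components = c("cjs", "clutch", "nestfate", "counts",
                                   "state")) {
  stopifnot(inherits(data, "ipm_data"))
  bad <- setdiff(components,
                 c("cjs", "clutch", "nestfate", "counts", "state"))
  if (length(bad)) {
    stop_validation("unknown component(s): ", paste(bad, collapse = ", "),
                    "; options are cjs, clutch, nestfate, counts, state")
  }
  priors <- .resolve_priors(priors, data)
  sdl <- .sampler_data(data, priors, components)
  T <- data$T
  nmiss <- nrow(sdl$missIdx)
  miss_names <- if (nmiss) sprintf("cov_miss[%d,%d]", sdl$missIdx[, 1] + 1,
                                   sdl$missIdx[, 2] + 1) else character()
  pn <- .param_names(T, miss_names)
  steps <- .init_steps(T, nmiss)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    init <- .init_state(sdl, priors, config$seed + ch)
    set.seed(config$seed + ch)
    res <- ipm_mcmc_cpp(sdl, init, steps, config$n_iter, config$n_burnin,
                        config$thin)
    colnames(res$draws) <- pn
    chains[[ch]] <- res$draws
    attr(chains[[ch]], "logpost") <- res$logpost
  }
  manifest <- data.frame(
    name = pn,
    type = c(rep("vital_rate", 9), rep("covariate_effect", 5),
             rep("year_sd", 6), "immigration",
             rep("year_effect", 6 * T), rep("immigration", T - 1),
             rep("latent_state", 2 + 4 * (T - 1)),
             rep("imputed_covariate", nmiss)))
  fit <- structure(list(chains = chains, manifest = manifest,
                        data = data, config = config, priors = priors,
                        components = components, years = data$years,
                        miss_idx = sdl$missIdx),
                   class = "ipm_fit")
  fit$rhat <- gelman_rubin(chains)
  fit$flagged_chains <- flag_chains(fit)
  fit$summary <- .summarize_draws(fit)
  fit
}

#' Fit one data component independently
#'
#' Fits a single likelihood component (with the same priors and parameter
#' manifest as the full IPM) to its own data alone, for comparing
#' independent and integrated posteriors.
#'
#' @param data An [ipm_data()] bundle.
#' @param which `"survival"` (mark-recapture CJS), `"clutch"` or
#'   `"nestfate"`.
#' @inheritParams fit_ipm
#' @return An `ipm_fit` restricted to the chosen component.
#' @export
fit_independent <- function(data, which = c("survival", "clutch", "nestfate"),
                            config = fit_config(profile = "test"),
                            priors = default_priors()) {
  which <- match.arg(which)
  comp <- switch(which, survival = "cjs", clutch = "clutch",
                 nestfate = "nestfate")
  has_rows <- switch(which,
    survival = length(data$captures$individual) > 0,
    clutch = nrow(data$repro) > 0,
    nestfate = nrow(data$repro) > 0)
  if (!has_rows) stop_validation("no data rows for component '", which, "'")
  fit_ipm(data, config, priors, components = comp)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}} from within-chain variance
#' W and between-chain variance B (no chain splitting).
#'
#' @param chains List of draw matrices (iterations x parameters), or an
#'   `ipm_fit`.
#' @return Named vector of R-hat values (`NA` for degenerate parameters).
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "ipm_fit")) chains <- chains$chains
  if (length(chains) < 2) {
    stop_validation("R-hat needs >= 2 chains; rerun with n_chains >= 2")
  }
  n <- nrow(chains[[1]])
  if (n < 10) stop_validation("R-hat needs >= 10 retained draws per chain")
  means <- matrix(sapply(chains, colMeans), ncol = length(chains))
  vars <- matrix(sapply(chains, function(m) apply(m, 2, var)),
                 ncol = length(chains))
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W == 0] <- NA_real_
  setNames(rhat, colnames(chains[[1]]))
}

#' Flag chains that prevent convergence
#'
#' A chain is flagged when the maximum R-hat over top-level parameters
#' exceeds the threshold but dropping that single chain brings it below.
#'
#' @param fit An `ipm_fit`.
#' @param threshold Convergence threshold (default 1.1).
#' @return Integer vector of flagged chain indices (possibly empty).
#' @export
flag_chains <- function(fit, threshold = 1.1) {
  chains <- fit$chains
  if (length(chains) < 3) return(integer())
  top <- intersect(.top_level_params(), colnames(chains[[1]]))
  sub <- lapply(chains, function(m) m[, top, drop = FALSE])
  full <- suppressWarnings(max(gelman_rubin(sub), na.rm = TRUE))
  if (!is.finite(full) || full <= threshold) return(integer())
  flagged <- integer()
  for (ch in seq_along(chains)) {
    r <- suppressWarnings(max(gelman_rubin(sub[-ch]), na.rm = TRUE))
    if (is.finite(r) && r <= threshold) flagged <- c(flagged, ch)
  }
  flagged
}

.summarize_draws <- function(fit, exclude_flagged = FALSE) {
  chains <- fit$chains
  if (exclude_flagged && length(fit$flagged_chains)) {
    keep <- setdiff(seq_along(chains), fit$flagged_chains)
    if (length(keep) >= 2) chains <- chains[keep]
  }
  all <- do.call(rbind, chains)
  data.frame(parameter = colnames(all),
             median = apply(all, 2, median),
             lower95 = apply(all, 2, quantile, 0.025),
             upper95 = apply(all, 2, quantile, 0.975),
             row.names = NULL)
}

#' Pooled posterior draws
#' @param fit An `ipm_fit`.
#' @param exclude_flagged Drop chains flagged by [flag_chains()].
#' @return One matrix of draws (all chains stacked).
#' @export
posterior_draws <- function(fit, exclude_flagged = FALSE) {
  chains <- fit$chains
  if (exclude_flagged && length(fit$flagged_chains)) {
    keep <- setdiff(seq_along(chains), fit$flagged_chains)
    if (length(keep) >= 2) chains <- chains[keep]
  }
  do.call(rbind, chains)
}
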