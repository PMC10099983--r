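#' Per-year vital rate draws on the natural scale
#'
#' Reconstructs the year-specific rates implied by each retained draw:
#' intercepts, covariate effects (with each draw's own imputed values for
#' missing covariates) and year random effects through the inverse link.
#'
#' @param fit An `ipm_fit`.
#' @param draws Optional pooled draw matrix (defaults to all chains).
#' @return List of draw x year matrices: `pB_Y`, `pB_A`, `CS_Y`, `CS_A`,
#'   `pNS`, `sN_Y`, `sN_A`, `sJ`, `sA`.
#' @export
vital_rate_draws <- function(fit, draws = NULL) {
  d <- draws %||% posterior_draws(fit)
  T <- fit$data$T
  n <- nrow(d)
  cv <- fit$data$covariates
  covmat <- function(x) {
    x[is.na(x)] <- 0
    matrix(x, n, T, byrow = TRUE)
  }
  rain_ph <- covmat(cv$rain_ph); temp_ph <- covmat(cv$temp_ph)
  rain_pf <- covmat(cv$rain_pf)
  mi <- fit$miss_idx
  if (!is.null(mi) && nrow(mi)) {
    for (k in seq_len(nrow(mi))) {
      v <- mi[k, 1] + 1L; t <- mi[k, 2] + 1L
      col <- d[, sprintf("cov_miss[%d,%d]", v, t)]
      if (v == 1) rain_ph[, t] <- col
      if (v == 2) temp_ph[, t] <- col
      if (v == 3) rain_pf[, t] <- col
    }
  }
  eps <- function(r) d[, sprintf("eps_%s[%d]", r, seq_len(T)), drop = FALSE]
  e_pB <- eps("pB"); e_CS <- eps("CS"); e_pNS <- eps("pNS")
  e_sN <- eps("sN"); e_sJ <- eps("sJ"); e_sA <- eps("sA")
  list(
    pB_Y = plogis(qlogis(d[, "pB_Y"]) + e_pB),
    pB_A = plogis(qlogis(d[, "pB_A"]) + e_pB),
    CS_Y = exp(log(d[, "CS_Y"]) + e_CS),
    CS_A = exp(log(d[, "CS_A"]) + e_CS),
    pNS = plogis(qlogis(d[, "pNS"]) + d[, "beta_rain_pNS"] * rain_ph +
                   d[, "beta_temp_pNS"] * temp_ph + e_pNS),
    sN_Y = plogis(qlogis(d[, "sN_Y"]) + d[, "beta_rain_sN"] * rain_ph +
                    d[, "beta_temp_sN"] * temp_ph + e_sN),
    sN_A = plogis(qlogis(d[, "sN_A"]) + d[, "beta_rain_sN"] * rain_ph +
                    d[, "beta_temp_sN"] * temp_ph + e_sN),
    sJ = plogis(qlogis(d[, "sJ"]) + d[, "beta_rain_sJ"] * rain_pf + e_sJ),
    sA = plogis(qlogis(d[, "sA"]) + e_sA))
}

#' Latent abundance and immigration draws
#'
#' @inheritParams vital_rate_draws
#' @return List of draw x year matrices `N_Y`, `N_A`, `ImmY`, `ImmA`,
#'   `Omega_tot` (immigration columns are `NA` for year 1).
#' @export
latent_state_draws <- function(fit, draws = NULL) {
  d <- draws %||% posterior_draws(fit)
  T <- fit$data$T
  n <- nrow(d)
  pick <- function(fmt, yrs) d[, sprintf(fmt, yrs), drop = FALSE]
  localY <- pick("localY[%d]", 2:T); ImmY <- pick("ImmY[%d]", 2:T)
  survA <- pick("survA[%d]", 2:T); ImmA <- pick("ImmA[%d]", 2:T)
  list(N_Y = cbind(d[, "N_Y[1]"], localY + ImmY),
       N_A = cbind(d[, "N_A[1]"], survA + ImmA),
       ImmY = cbind(NA_real_, ImmY), ImmA = cbind(NA_real_, ImmA),
       Omega_tot = cbind(NA_real_, pick("Omega_tot[%d]", 2:T)))
}

#' Posterior predictive check table for the count streams
#'
#' For every observed count stream and year, draws a Poisson replicate
#' around each retained draw's expectation, and reports the predictive
#' median and 95% interval, the observation, and whether it is covered.
#'
#' @param fit An `ipm_fit`.
#' @param seed Seed for the predictive draws.
#' @param exclude_flagged Drop flagged chains.
#' @return List with `table` (rows = years x streams) and `coverage`
#'   (empirical coverage of the 95% predictive intervals).
#' @export
posterior_predictive_table <- function(fit, seed = 1,
                                       exclude_flagged = FALSE) {
  set.seed(seed)
  d <- posterior_draws(fit, exclude_flagged)
  rates <- vital_rate_draws(fit, d)
  lat <- latent_state_draws(fit, d)
  T <- fit$data$T
  pCapB <- fit$data$counts$pCapB
  pCapB[is.na(pCapB)] <- mean(pCapB, na.rm = TRUE)
  mus <- list(
    first_clutches = lat$N_Y * rates$pB_Y + lat$N_A * rates$pB_A,
    eggs = lat$N_Y * rates$pB_Y * rates$CS_Y +
      lat$N_A * rates$pB_A * rates$CS_A,
    fledglings = lat$N_Y * rates$pB_Y * rates$CS_Y * rates$pNS * rates$sN_Y +
      lat$N_A * rates$pB_A * rates$CS_A * rates$pNS * rates$sN_A,
    newly_ringed = sweep(lat$Omega_tot, 2, pCapB, "*"))
  rows <- list()
  for (stream in names(mus)) {
    mu <- mus[[stream]]
    obs <- fit$data$counts[[stream]]
    for (t in seq_len(T)) {
      if (all(is.na(mu[, t]))) {
        rows[[length(rows) + 1]] <- data.frame(
          stream = stream, year = fit$years[t], lower95 = NA, median = NA,
          upper95 = NA, observed = obs[t], covered = NA)
        next
      }
      yrep <- rpois(nrow(mu), mu[, t])
      qq <- quantile(yrep, c(.025, .5, .975))
      rows[[length(rows) + 1]] <- data.frame(
        stream = stream, year = fit$years[t], lower95 = qq[1],
        median = qq[2], upper95 = qq[3], observed = obs[t],
        covered = obs[t] >= qq[1] & obs[t] <= qq[3])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, coverage = mean(tab$covered, na.rm = TRUE))
}

#' Posterior-median time-average parameter set
#'
#' @param fit An `ipm_fit`.
#' @param exclude_flagged Drop flagged chains.
#' @return Named list of scalar median rates (time-averaged per draw before
#'   taking the median), expected immigrant totals and the last latent state.
#' @export
posterior_medians <- function(fit, exclude_flagged = FALSE) {
  d <- posterior_draws(fit, exclude_flagged)
  rates <- vital_rate_draws(fit, d)
  lat <- latent_state_draws(fit, d)
  T <- fit$data$T
  med <- lapply(rates, function(m) median(rowMeans(m)))
  med$Omega_tot <- median(rowMeans(lat$Omega_tot[, -1, drop = FALSE]))
  med$q <- median(d[, "q_imm"])
  med$last_state <- c(round(median(lat$N_Y[, T])),
                      round(median(lat$N_A[, T])))
  med
}

#' Stochastic forward projection from posterior medians
#'
#' Projects the population forward from the last estimated state using the
#' posterior medians of the time-averaged vital rates and immigration, with
#' full demographic stochasticity ([stochastic_project()]).
#'
#' @param fit An `ipm_fit`.
#' @param horizon Years to project (>= 1).
#' @param reps Replicate trajectories.
#' @param seed Seed.
#' @param exclude_flagged Drop flagged chains.
#' @return Data frame per projected year: total-population quantiles
#'   (`lower95`, `median`, `upper95`).
#' @export
forward_projection_check <- function(fit, horizon = 10, reps = 1000,
                                     seed = 1, exclude_flagged = FALSE) {
  if (horizon < 1) stop_validation("horizon must be >= 1")
  med <- posterior_medians(fit, exclude_flagged)
  .project_from_medians(med, horizon, reps, seed)
}

.project_from_medians <- function(med, horizon, reps, seed) {
  rates <- vital_rate_series(
    pB = rbind(rep(med$pB_Y, horizon), rep(med$pB_A, horizon)),
    CS = rbind(rep(med$CS_Y, horizon), rep(med$CS_A, horizon)),
    pNS = rep(med$pNS, horizon),
    sN = rbind(rep(med$sN_Y, horizon), rep(med$sN_A, horizon)),
    sJ = rep(med$sJ, horizon), sA = rep(med$sA, horizon))
  imm <- rbind(rep(med$q * med$Omega_tot, horizon),
               rep((1 - med$q) * med$Omega_tot, horizon))
  proj <- stochastic_project(rates, imm, med$last_state, reps = reps,
                             seed = seed)
  Ntot <- proj$N_Y + proj$N_A
  data.frame(step = 0:horizon,
             lower95 = apply(Ntot, 2, quantile, 0.025),
             median = apply(Ntot, 2, median),
             upper95 = apply(Ntot, 2, quantile, 0.975))
}
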