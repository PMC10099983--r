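LTRE_GROUPS <- c(pB_Y = "reproduction", pB_A = "reproduction",
                 CS_Y = "reproduction", CS_A = "reproduction",
                 pNS = "reproduction", sN_Y = "reproduction",
                 sN_A = "reproduction", sJ = "survival", sA = "survival",
                 omega_Y = "immigration", omega_A = "immigration",
                 n_Y = "structure")

#' Analytic sensitivities of annual growth to its components
#'
#' Partial derivatives of [lambda_decomposed()] with respect to every
#' component, evaluated at a reference point (typically temporal means).
#' Growth is affine in adult survival and the immigration rates, so their
#' sensitivities are exactly 1.
#'
#' @param theta_bar Named reference vector ([theta_names()]).
#' @return Named vector of partial derivatives in the same order.
#' @export
sensitivities <- function(theta_bar) {
  th <- .check_theta(theta_bar)
  F_Y <- th["pB_Y"] * th["CS_Y"] * th["pNS"] * th["sN_Y"]
  F_A <- th["pB_A"] * th["CS_A"] * th["pNS"] * th["sN_A"]
  nY <- th["n_Y"]; nA <- 1 - nY; sJ <- th["sJ"]
  s <- c(
    pB_Y = nY * 0.5 * sJ * th[["CS_Y"]] * th[["pNS"]] * th[["sN_Y"]],
    pB_A = nA * 0.5 * sJ * th[["CS_A"]] * th[["pNS"]] * th[["sN_A"]],
    CS_Y = nY * 0.5 * sJ * th[["pB_Y"]] * th[["pNS"]] * th[["sN_Y"]],
    CS_A = nA * 0.5 * sJ * th[["pB_A"]] * th[["pNS"]] * th[["sN_A"]],
    pNS = 0.5 * sJ * (nY * th[["pB_Y"]] * th[["CS_Y"]] * th[["sN_Y"]] +
                        nA * th[["pB_A"]] * th[["CS_A"]] * th[["sN_A"]]),
    sN_Y = nY * 0.5 * sJ * th[["pB_Y"]] * th[["CS_Y"]] * th[["pNS"]],
    sN_A = nA * 0.5 * sJ * th[["pB_A"]] * th[["CS_A"]] * th[["pNS"]],
    sJ = 0.5 * (nY * F_Y + nA * F_A),
    sA = 1, omega_Y = 1, omega_A = 1,
    n_Y = 0.5 * sJ * (F_Y - F_A))
  unname2 <- setNames(as.numeric(s), theta_names())
  unname2
}

.check_theta_series <- function(theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) != 12 && ncol(theta) == 12) theta <- t(theta)
  if (is.null(rownames(theta))) rownames(theta) <- theta_names()
  theta <- theta[theta_names(), , drop = FALSE]
  theta
}

.new_contributions <- function(contrib, design, reference, total_direct = NA,
                               extra = NULL) {
  out <- list(contributions = contrib,
              groups = LTRE_GROUPS[names(contrib)],
              design = design, reference = reference,
              total = sum(contrib, na.rm = TRUE),
              total_direct = total_direct)
  out <- c(out, extra)
  class(out) <- "ltre_contributions"
  out
}

#' Random-design transient LTRE
#'
#' Decomposes among-year variance in realized growth into per-component
#' contributions \eqn{c_i = \sum_j cov(\theta_i, \theta_j) s_i s_j} with
#' sensitivities evaluated at the temporal means; the total equals
#' \eqn{s' \Sigma s}, a first-order approximation of var(\eqn{\lambda_t}).
#'
#' @param theta_series 12 x n matrix of per-year component values (rows as
#'   [theta_names()]).
#' @return An `ltre_contributions` object (reference `var_lambda`).
#' @export
random_design <- function(theta_series) {
  th <- .check_theta_series(theta_series)
  if (ncol(th) < 3) stop_validation("random design needs >= 3 years")
  s <- sensitivities(rowMeans(th))
  S <- cov(t(th))
  contrib <- as.numeric(S %*% s) * s
  names(contrib) <- theta_names()
  .new_contributions(contrib, "random", "var_lambda")
}

#' Fixed-design transient LTRE
#'
#' Contribution of the change in each component between consecutive years to
#' the change in annual growth, \eqn{c_i = (\theta_{i,t+1} - \theta_{i,t})
#' s_i}, with sensitivities evaluated at the midpoint of the two years
#' (which makes the sum identity to \eqn{\Delta\lambda_t} exact for the
#' bilinear part of the growth function).
#'
#' @param theta_series 12 x n matrix (n >= 2); one set of contributions is
#'   returned per year-to-year step.
#' @return An `ltre_contributions` object; `contributions` is a 12 x (n-1)
#'   matrix, `total` the per-step sums, and `delta_lambda` the exact change
#'   in [lambda_decomposed()] growth for comparison.
#' @export
fixed_design <- function(theta_series) {
  th <- .check_theta_series(theta_series)
  if (ncol(th) < 2) stop_validation("fixed design needs >= 2 years")
  n <- ncol(th)
  d <- th[, -1, drop = FALSE] - th[, -n, drop = FALSE]
  s_mid <- sapply(seq_len(n - 1), function(j)
    sensitivities((th[, j] + th[, j + 1]) / 2))
  contrib <- d * s_mid
  lam <- apply(th, 2, lambda_decomposed)
  out <- list(contributions = contrib, groups = LTRE_GROUPS[rownames(contrib)],
              design = "fixed", reference = "delta_lambda",
              total = colSums(contrib), delta_lambda = diff(lam))
  class(out) <- "ltre_contributions"
  out
}

# per-capita projection recursion over a period: returns log geometric
# growth; `free` propagates structure, `frozen` uses the supplied n_Y series
.period_loggrowth <- function(th, free = TRUE) {
  L <- ncol(th)
  if (free) {
    nY <- th["n_Y", 1]
    N <- c(nY, 1 - nY)
    loglam <- 0
    for (j in seq_len(L)) {
      F_Y <- th["pB_Y", j] * th["CS_Y", j] * th["pNS", j] * th["sN_Y", j]
      F_A <- th["pB_A", j] * th["CS_A", j] * th["pNS", j] * th["sN_A", j]
      Ntot <- sum(N)
      N2 <- c(0.5 * th["sJ", j] * (F_Y * N[1] + F_A * N[2]) +
                th["omega_Y", j] * Ntot,
              th["sA", j] * Ntot + th["omega_A", j] * Ntot)
      loglam <- loglam + log(sum(N2) / Ntot)
      N <- N2 / sum(N2) * 1  # renormalize scale to avoid under/overflow
    }
    loglam / L
  } else {
    mean(log(apply(th, 2, lambda_decomposed)))
  }
}

# proportional perturbation of one component's within-period values; if the
# upward move would leave the parameter domain (values at a bound), the
# perturbation is flipped downward and the signed epsilon returned
.perturb_series <- function(th, i, eps, what = c("mean", "sd")) {
  what <- match.arg(what)
  up <- .theta_upper()[i]
  shifted <- function(e) {
    if (what == "mean") th[i, ] * (1 + e)
    else { m <- mean(th[i, ]); m + (th[i, ] - m) * (1 + e) }
  }
  v <- shifted(eps)
  if (any(v > up | v < 0)) {
    eps <- -eps
    v <- shifted(eps)
    v <- pmin(pmax(v, 0), up)   # zero-mean rows remain at their bound
  }
  out <- th
  out[i, ] <- v
  list(series = out, eps = eps)
}

#' Real-time elasticities of geometric growth over a period
#'
#' Numerical proportional perturbation of each component's within-period
#' values: the mean elasticity scales all values by `1 + eps`, the SD
#' elasticity scales deviations from the period mean. The total response is
#' measured on the free projection recursion (structure re-propagates); the
#' direct part on a frozen-structure run (growth evaluated at the baseline
#' yearling fractions); the structure-mediated (indirect) part is their
#' difference. For the yearling fraction itself only a direct term is
#' defined (structure is endogenous in the free recursion).
#'
#' @param theta_series 12 x n matrix of per-year components.
#' @param period Integer indices of the period's years within the series.
#' @param eps Relative perturbation size.
#' @return Data frame per parameter: `e_mu_direct`, `e_mu_indirect`,
#'   `e_sigma_direct`, `e_sigma_indirect` (`NA` mean elasticity where a
#'   period mean is zero; zero SD elasticities for constant parameters).
#' @export
realtime_elasticities <- function(theta_series, period = NULL, eps = 1e-4) {
  th <- .check_theta_series(theta_series)
  if (is.null(period)) period <- seq_len(ncol(th))
  if (any(period < 1 | period > ncol(th))) {
    stop_validation("period indices outside the series")
  }
  th <- th[, period, drop = FALSE]
  base_free <- .period_loggrowth(th, free = TRUE)
  base_froz <- .period_loggrowth(th, free = FALSE)
  nm <- theta_names()
  out <- data.frame(parameter = nm, e_mu_direct = NA_real_,
                    e_mu_indirect = NA_real_, e_sigma_direct = 0,
                    e_sigma_indirect = 0)
  for (i in seq_along(nm)) {
    m <- mean(th[i, ])
    varies <- sd(th[i, ]) > 0
    if (m != 0) {
      pm <- .perturb_series(th, i, eps, "mean")
      d_dir <- (.period_loggrowth(pm$series, FALSE) - base_froz) / pm$eps
      if (nm[i] == "n_Y") {
        out$e_mu_direct[i] <- d_dir
        out$e_mu_indirect[i] <- 0
      } else {
        d_tot <- (.period_loggrowth(pm$series, TRUE) - base_free) / pm$eps
        out$e_mu_direct[i] <- d_dir
        out$e_mu_indirect[i] <- d_tot - d_dir
      }
    }
    if (varies) {
      ps <- .perturb_series(th, i, eps, "sd")
      d_dir <- (.period_loggrowth(ps$series, FALSE) - base_froz) / ps$eps
      out$e_sigma_direct[i] <- d_dir
      if (nm[i] == "n_Y") {
        out$e_sigma_indirect[i] <- 0
      } else {
        d_tot <- (.period_loggrowth(ps$series, TRUE) - base_free) / ps$eps
        out$e_sigma_indirect[i] <- d_tot - d_dir
      }
    }
  }
  out
}

#' Period-design transient LTRE
#'
#' Decomposes the change in log geometric mean growth between two
#' equal-length periods into contributions of changes in component means and
#' standard deviations, each split into direct and structure-mediated parts:
#' \deqn{c_i = (\log\mu_{i,P2} - \log\mu_{i,P1})(\bar e^T_{\mu_i} +
#'   \bar e^{\hat n}_{\mu_i}) + (\log\sigma_{i,P2} - \log\sigma_{i,P1})
#'   (\bar e^T_{\sigma_i} + \bar e^{\hat n}_{\sigma_i})}
#' Elasticities are the average of the two periods' real-time elasticities.
#'
#' @param theta_series 12 x n matrix.
#' @param period1,period2 Equal-length integer index vectors.
#' @param eps Perturbation size for [realtime_elasticities()].
#' @return An `ltre_contributions` object; `components` holds the four-way
#'   split, `delta_log_lambda_g` the directly computed change.
#' @export
period_design <- function(theta_series, period1, period2, eps = 1e-4) {
  th <- .check_theta_series(theta_series)
  if (length(period1) != length(period2)) {
    stop_validation("the two periods must have the same duration")
  }
  e1 <- realtime_elasticities(th, period1, eps)
  e2 <- realtime_elasticities(th, period2, eps)
  nm <- theta_names()
  m1 <- rowMeans(th[, period1, drop = FALSE])
  m2 <- rowMeans(th[, period2, drop = FALSE])
  s1 <- apply(th[, period1, drop = FALSE], 1, sd)
  s2 <- apply(th[, period2, drop = FALSE], 1, sd)
  emu_d <- (e1$e_mu_direct + e2$e_mu_direct) / 2
  emu_i <- (e1$e_mu_indirect + e2$e_mu_indirect) / 2
  esd_d <- (e1$e_sigma_direct + e2$e_sigma_direct) / 2
  esd_i <- (e1$e_sigma_indirect + e2$e_sigma_indirect) / 2
  dmu <- log(m2) - log(m1)
  dmu[m1 == 0 & m2 == 0] <- 0
  dsd <- log(s2) - log(s1)
  dsd[s1 == 0 & s2 == 0] <- 0
  if (any(xor(s1 == 0, s2 == 0))) {
    warning("sigma zero in exactly one period for: ",
            paste(nm[xor(s1 == 0, s2 == 0)], collapse = ", "),
            "; sigma terms flagged missing and excluded from the total")
    dsd[xor(s1 == 0, s2 == 0)] <- NA
  }
  comp <- cbind(mu_direct = dmu * emu_d, mu_indirect = dmu * emu_i,
                sigma_direct = dsd * esd_d, sigma_indirect = dsd * esd_i)
  rownames(comp) <- nm
  contrib <- rowSums(comp, na.rm = TRUE)
  dlg <- .period_loggrowth(th[, period2, drop = FALSE], TRUE) -
    .period_loggrowth(th[, period1, drop = FALSE], TRUE)
  .new_contributions(contrib, "period", "delta_log_lambda_g",
                     extra = list(components = comp,
                                  delta_log_lambda_g = dlg,
                                  elasticities = list(p1 = e1, p2 = e2)))
}

#' Apply a transient LTRE design to every posterior draw
#'
#' Assembles, for each retained draw, the per-year component series from the
#' sampled vital rates and latent states (per-capita immigration rates
#' \eqn{\omega_a[t] = Imm_a[t+1]/N_{tot}[t]}, yearling fraction from the
#' latent age structure) and runs the chosen design, returning draw-indexed
#' contributions with grouped posterior summaries.
#'
#' @param fit An `ipm_fit`.
#' @param design `"random"`, `"fixed"` or `"period"`.
#' @param period1,period2 Periods for the period design (year-step indices).
#' @param n_draws Subsample size (default all pooled draws).
#' @param exclude_flagged Drop chains flagged as non-converged.
#' @return An object of class `posterior_ltre`: `draws` (draw x parameter
#'   contribution matrix; for the fixed design, per-step totals are
#'   averaged), `summary` (per-parameter median and 95% CrI) and
#'   `group_summary`.
#' @export
posterior_ltre <- function(fit, design = c("random", "fixed", "period"),
                           period1 = NULL, period2 = NULL, n_draws = NULL,
                           exclude_flagged = FALSE) {
  if (!design[1] %in% c("random", "fixed", "period")) {
    stop_validation("unknown design '", design[1],
                    "'; options: random, fixed, period")
  }
  design <- match.arg(design)
  thetas <- theta_series_draws(fit, exclude_flagged = exclude_flagged)
  n <- length(thetas)
  if (!is.null(n_draws) && n_draws < n) {
    thetas <- thetas[round(seq(1, n, length.out = n_draws))]
  }
  per_draw <- lapply(thetas, function(th) {
    res <- switch(design,
      random = random_design(th),
      fixed = fixed_design(th),
      period = period_design(th, period1, period2))
    if (design == "fixed") rowMeans(res$contributions) else res$contributions
  })
  M <- do.call(rbind, per_draw)
  qs <- function(x) c(median = median(x), lower95 = quantile(x, .025,
                      names = FALSE), upper95 = quantile(x, .975,
                      names = FALSE))
  summ <- data.frame(parameter = colnames(M),
                     group = LTRE_GROUPS[colnames(M)],
                     t(apply(M, 2, qs)), row.names = NULL)
  G <- sapply(split(seq_len(ncol(M)), LTRE_GROUPS[colnames(M)]),
              function(ix) rowSums(M[, ix, drop = FALSE]))
  gsum <- data.frame(group = colnames(G), t(apply(G, 2, qs)),
                     row.names = NULL)
  structure(list(draws = M, group_draws = G, summary = summ,
                 group_summary = gsum, design = design),
            class = "posterior_ltre")
}

#' Per-draw component series from a fitted IPM
#'
#' @param fit An `ipm_fit`.
#' @param exclude_flagged Drop flagged chains.
#' @return List of 12 x (T-1) theta matrices, one per pooled draw.
#' @export
theta_series_draws <- function(fit, exclude_flagged = FALSE) {
  d <- posterior_draws(fit, exclude_flagged)
  rates <- vital_rate_draws(fit, d)
  lat <- latent_state_draws(fit, d)
  T <- fit$data$T
  idx <- seq_len(T - 1)
  Ntot <- lat$N_Y + lat$N_A
  lapply(seq_len(nrow(d)), function(k) {
    rbind(pB_Y = rates$pB_Y[k, idx], pB_A = rates$pB_A[k, idx],
          CS_Y = rates$CS_Y[k, idx], CS_A = rates$CS_A[k, idx],
          pNS = rates$pNS[k, idx],
          sN_Y = rates$sN_Y[k, idx], sN_A = rates$sN_A[k, idx],
          sJ = rates$sJ[k, idx], sA = rates$sA[k, idx],
          omega_Y = lat$ImmY[k, idx + 1] / Ntot[k, idx],
          omega_A = lat$ImmA[k, idx + 1] / Ntot[k, idx],
          n_Y = lat$N_Y[k, idx] / Ntot[k, idx])
  })
}
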