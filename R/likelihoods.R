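#' Link-scale linear predictor for a vital rate
#'
#' Vital rates vary among years through normally distributed random year
#' effects on the link scale, and (for nest success, nestling survival and
#' juvenile survival) through standardized weather covariates. Components a
#' rate does not have (e.g. covariates on clutch size) simply contribute 0.
#'
#' @param model List describing one rate: `link` (`"logit"` or `"log"`),
#'   `intercept` (link scale; named per age class or a single value),
#'   optional `beta_rain`, `beta_temp`, and `eps` (per-year random effects).
#' @param age `"yearling"` or `"adult"` (ignored for single-intercept rates).
#' @param year Year index into `eps`.
#' @param covariates Named list/vector with `rain` and/or `temp`
#'   (standardized); required only if the model has the matching slope.
#' @return The rate on its natural scale.
#' @export
linear_predictor <- function(model, age = "adult", year = 1,
                             covariates = list()) {
  ic <- model$intercept
  eta <- if (!is.null(names(ic))) unname(ic[age]) else ic
  for (term in c("rain", "temp")) {
    b <- model[[paste0("beta_", term)]]
    if (!is.null(b) && b != 0) {
      x <- covariates[[term]]
      if (is.null(x) || is.na(x)) {
        stop_validation("missing '", term, "' covariate (imputation is the ",
                        "sampler's job)")
      }
      eta <- eta + b * x
    }
  }
  if (!is.null(model$eps)) eta <- eta + model$eps[year]
  switch(model$link, logit = plogis(eta), log = exp(eta),
         stop_validation("link must be 'logit' or 'log'"))
}

.age_index <- function(age) match(age, AGE_CLASSES)

#' Age-structured Cormack-Jolly-Seber log-likelihood
#'
#' Individual-by-individual likelihood of detection histories conditional on
#' first capture. Nestling-ringed birds survive their first interval with
#' juvenile survival `sJ` and are yearlings at their first anniversary;
#' afterwards (and for adult-ringed birds throughout) survival is `sA`.
#' Recapture probability is breeding probability times the probability of
#' identification given breeding: `p[a, t] = pB[a, t] * pCapB[t]`.
#'
#' @param histories A `capture_histories` object whose years map to indices
#'   `1..T` (see [capture_histories()]).
#' @param sJ,sA Survival over interval `t -> t+1`, length `T - 1` (or `T`;
#'   the last entry is then unused).
#' @param pB 2 x T matrix of breeding probabilities.
#' @param pCapB Length-T identification probabilities.
#' @return Log-likelihood (0 for an empty history set).
#' @export
cjs_loglik <- function(histories, sJ, sA, pB, pCapB) {
  pB <- .as_age_matrix(pB)
  T <- ncol(pB)
  for (v in list(sJ, sA, pB, pCapB)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop_validation("CJS probabilities must lie in [0,1]")
    }
  }
  p <- pB * rep(pCapB, each = 2)  # detection prob by age and occasion
  dimnames(p) <- NULL
  n <- length(histories$individual)
  if (!n) return(0)
  year0 <- min(histories$years)
  total <- 0
  for (i in seq_len(n)) {
    det <- histories$det[[i]]
    r <- histories$first_year[i] - year0 + 1L
    juv <- histories$ring_age[i] == "nestling"
    # age class index at occasion t (for detection): yearling only at the
    # first anniversary of a nestling-ringed bird
    age_at <- function(t) if (juv && t == r + 1L) 1L else 2L
    phi_at <- function(t) if (juv && t == r) sJ[t] else sA[t]  # t -> t+1
    # chi[t]: P(never seen after occasion t | alive at t)
    chi <- numeric(T)
    chi[T] <- 1
    if (T > r) for (t in (T - 1):r) {
      chi[t] <- 1 - phi_at(t) + phi_at(t) * (1 - p[age_at(t + 1L), t + 1L]) *
        chi[t + 1L]
    }
    occ <- seq.int(r, T)
    seen <- occ[det == 1]
    L <- max(seen)
    ll <- 0
    if (L > r) for (t in r:(L - 1L)) {
      ll <- ll + log(phi_at(t)) +
        log(if ((t + 1L) %in% seen) p[age_at(t + 1L), t + 1L]
            else 1 - p[age_at(t + 1L), t + 1L])
    }
    total <- total + ll + log(chi[L])
  }
  unname(total)
}

#' Build age-structured m-arrays from capture histories
#'
#' Summarizes histories into the standard release/first-recapture arrays: one
#' for birds released as nestlings (first interval with juvenile survival)
#' and one for birds released as full-grown adults, including re-releases of
#' recaptured nestling-origin birds.
#'
#' @param histories A `capture_histories` object.
#' @return List of `(T-1) x T` integer matrices `juv` and `ad` (columns
#'   1..T-1 = first recapture at occasion 2..T; last column = never seen
#'   again).
#' @export
build_marray <- function(histories) {
  T <- length(histories$years)
  year0 <- min(histories$years)
  marrJ <- matrix(0L, T - 1, T)
  marrA <- matrix(0L, T - 1, T)
  for (i in seq_along(histories$individual)) {
    det <- histories$det[[i]]
    r <- histories$first_year[i] - year0 + 1L
    occ <- seq.int(r, T)
    seen <- occ[det == 1]
    juv <- histories$ring_age[i] == "nestling"
    rel <- seen[-length(seen)]
    rec <- seen[-1]
    if (length(rel)) {
      first <- juv & rel == r
      for (k in seq_along(rel)) {
        if (first[k]) marrJ[rel[k], rec[k] - 1L] <- marrJ[rel[k], rec[k] - 1L] + 1L
        else marrA[rel[k], rec[k] - 1L] <- marrA[rel[k], rec[k] - 1L] + 1L
      }
    }
    last <- max(seen)
    if (last < T) {
      if (juv && last == r) marrJ[last, T] <- marrJ[last, T] + 1L
      else marrA[last, T] <- marrA[last, T] + 1L
    }
  }
  list(juv = marrJ, ad = marrA)
}

#' CJS log-likelihood from m-arrays (multinomial form)
#'
#' Identical to [cjs_loglik()] on the same data (the multinomial coefficient
#' is omitted, matching the product-over-individuals form).
#'
#' @param marr List from [build_marray()].
#' @inheritParams cjs_loglik
#' @return Log-likelihood.
#' @export
cjs_marray_loglik <- function(marr, sJ, sA, pB, pCapB) {
  pB <- .as_age_matrix(pB)
  T <- ncol(pB)
  p <- pB * rep(pCapB, each = 2)
  dimnames(p) <- NULL
  ll <- 0
  for (arr in c("juv", "ad")) {
    m <- marr[[arr]]
    for (t in seq_len(T - 1)) {
      if (sum(m[t, ]) == 0) next
      pr <- numeric(T)
      surv <- 1
      for (j in (t + 1):T) {
        phi <- if (arr == "juv" && j == t + 1) sJ[t] else sA[j - 1]
        a <- if (arr == "juv" && j == t + 1) 1L else 2L
        pr[j - 1] <- surv * phi * p[a, j]
        surv <- surv * phi * (1 - p[a, j])
      }
      pr[T] <- 1 - sum(pr[seq_len(T - 1)])
      sel <- m[t, ] > 0
      ll <- ll + sum(m[t, sel] * log(pr[sel]))
    }
  }
  unname(ll)
}

#' Poisson log-likelihood for clutch sizes of known-age mothers
#'
#' @param records Data frame with columns `clutch`, `age` (`"yearling"` or
#'   `"adult"`), and `year` (index `1..T`).
#' @param CS 2 x T matrix of expected clutch sizes.
#' @return Log-likelihood (each term floored at -1e12 as a finite guard).
#' @export
clutch_loglik <- function(records, CS) {
  CS <- .as_age_matrix(CS)
  if (!nrow(records)) return(0)
  if (any(!records$age %in% AGE_CLASSES)) {
    stop_validation("clutch records must have known mother age")
  }
  mu <- CS[cbind(.age_index(records$age), records$year)]
  sum(pmax(dpois(records$clutch, mu, log = TRUE), -1e12))
}

#' Log-likelihood of nest fates (complete failure and per-egg survival)
#'
#' A nest fledging `f > 0` young contributes success (probability `pNS`)
#' times a Binomial(`clutch`, `sN`) term; a nest with zero fledglings is a
#' mixture of complete failure (`1 - pNS`) and success with all eggs lost.
#'
#' @param records Data frame with `clutch`, `fledged`, `age`, `year`.
#' @param pNS Length-T nest success probabilities.
#' @param sN 2 x T matrix of per-egg survival given no complete failure.
#' @return Log-likelihood.
#' @export
nest_fate_loglik <- function(records, pNS, sN) {
  sN <- .as_age_matrix(sN)
  if (!nrow(records)) return(0)
  if (any(records$fledged > records$clutch)) {
    stop_validation("fledged must not exceed clutch")
  }
  a <- .age_index(records$age)
  t <- records$year
  s <- sN[cbind(a, t)]
  ns <- pNS[t]
  f <- records$fledged
  ll <- ifelse(f > 0,
               log(ns) + dbinom(f, records$clutch, s, log = TRUE),
               log((1 - ns) + ns * (1 - s)^records$clutch))
  sum(pmax(ll, -1e12))
}

.pois_ll <- function(x, mu) {
  ifelse(mu > 0, dpois(x, mu, log = TRUE), ifelse(x == 0, 0, -Inf))
}

#' Log-likelihood of the annual population-level count streams
#'
#' First clutches, total eggs and total fledglings are Poisson around their
#' latent expectations; newly ringed adult females are Poisson around the
#' expected immigrant count thinned by the identification probability.
#'
#' @param counts Data frame from [build_population_counts()].
#' @param N 2 x T matrix of latent abundances (rows yearling/adult).
#' @param rates A [vital_rate_series()].
#' @param Omega 2 x T matrix of expected immigrant counts arriving before
#'   the census of year t (`NA` where the stream is not modelled, e.g. t = 1).
#' @param pCapB Length-T identification probabilities.
#' @return Log-likelihood (with a `-Inf` guard for impossible zeros).
#' @export
counts_loglik <- function(counts, N, rates, Omega, pCapB) {
  T <- ncol(N)
  mu_B <- colSums(N * rates$pB)
  mu_E <- colSums(N * rates$pB * rates$CS)
  mu_F <- colSums(N * rates$pB * rates$CS *
                    rep(rates$pNS, each = 2) * rates$sN)
  ll <- sum(.pois_ll(counts$first_clutches, mu_B)) +
    sum(.pois_ll(counts$eggs, mu_E)) +
    sum(.pois_ll(counts$fledglings, mu_F))
  mu_R <- pCapB * colSums(Omega)
  use <- !is.na(mu_R)
  unname(ll + sum(.pois_ll(counts$newly_ringed[use], mu_R[use])))
}

#' Log-likelihood of latent state transitions
#'
#' Local recruits are Poisson around half (female share) the fecundity
#' output times juvenile survival; adult survivors are Binomial over the
#' whole previous population; immigrant counts are Poisson around their
#' expectations.
#'
#' @param N 2 x T latent abundances.
#' @param imm 2 x T immigrant counts (column t = arrivals before census of
#'   year t; column 1 unused).
#' @param rates A [vital_rate_series()].
#' @param Omega 2 x T expected immigrant counts (column 1 may be `NA`).
#' @return Log-likelihood; `-Inf` when survivors exceed available birds or
#'   any implied local count is negative.
#' @export
state_transition_loglik <- function(N, imm, rates, Omega) {
  T <- ncol(N)
  Fec <- rates$pB * rates$CS * rep(rates$pNS, each = 2) * rates$sN
  ll <- 0
  for (t in seq_len(T - 1)) {
    localY <- N[1, t + 1] - imm[1, t + 1]
    survA <- N[2, t + 1] - imm[2, t + 1]
    Ntot <- sum(N[, t])
    if (localY < 0 || survA < 0 || survA > Ntot) return(-Inf)
    mu_rec <- 0.5 * rates$sJ[t] * sum(N[, t] * Fec[, t])
    ll <- ll + .pois_ll(localY, mu_rec) +
      dbinom(survA, Ntot, rates$sA[t], log = TRUE) +
      .pois_ll(imm[1, t + 1], Omega[1, t + 1]) +
      .pois_ll(imm[2, t + 1], Omega[2, t + 1])
    if (!is.finite(ll)) return(-Inf)
  }
  unname(ll)
}
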