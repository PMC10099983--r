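#' @useDynLib nestipm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rpois rnorm runif quantile cor var median sd
#'   plogis qlogis setNames complete.cases dpois dbinom aggregate
NULL

AGE_CLASSES <- c("yearling", "adult")

#' Names and order of the per-year demographic parameter vector
#'
#' The population growth rate of the female-based two-age-class model can be
#' written as a function of twelve per-year quantities: age-specific breeding
#' probabilities, clutch sizes, nest success, nestling survival, juvenile and
#' adult annual survival, per-capita immigration rates and the yearling
#' proportion of the population. This fixed ordering is shared by
#' [lambda_decomposed()], [sensitivities()] and all LTRE routines.
#'
#' @return Character vector of length 12.
#' @export
theta_names <- function() {
  c("pB_Y", "pB_A", "CS_Y", "CS_A", "pNS", "sN_Y", "sN_A",
    "sJ", "sA", "omega_Y", "omega_A", "n_Y")
}

# bounds used for validation; CS upper bound is the biological prior cap
.theta_lower <- function() setNames(rep(0, 12), theta_names())
.theta_upper <- function() {
  # sJ is allowed up to 2 because realized juvenile survival is defined
  # against the constant female share 0.5 and can exceed 1 in tiny broods
  up <- c(1, 1, Inf, Inf, 1, 1, 1, 2, 1, Inf, Inf, 1)
  setNames(up, theta_names())
}

.check_theta <- function(theta) {
  nm <- theta_names()
  if (is.null(names(theta))) names(theta) <- nm[seq_along(theta)]
  if (!all(nm %in% names(theta))) {
    stop_validation("theta must contain components: ",
                    paste(setdiff(nm, names(theta)), collapse = ", "))
  }
  theta <- theta[nm]
  lo <- .theta_lower(); up <- .theta_upper()
  bad <- which(theta < lo | theta > up | !is.finite(theta) & !is.infinite(up))
  if (length(bad)) {
    stop_validation("theta component(s) out of bounds: ",
                    paste(nm[bad], collapse = ", "))
  }
  theta
}

#' Expected fledglings per female (age-specific fecundity)
#'
#' Fecundity is the product of breeding probability, clutch size, the
#' probability that the nest escapes complete failure, and per-egg survival to
#' fledging given no complete failure.
#'
#' @param pB Breeding probability in `[0,1]`.
#' @param CS Expected clutch size (eggs, non-negative).
#' @param pNS Nest success probability in `[0,1]`.
#' @param sN Per-egg survival to fledging in `[0,1]`.
#' @return Expected number of fledglings per female. Vectorized.
#' @examples
#' fecundity(0.9, 6.5, 0.8, 0.9)
#' @export
fecundity <- function(pB, CS, pNS, sN) {
  for (comp in c("pB", "pNS", "sN")) {
    v <- get(comp)
    if (any(!is.finite(v) | v < 0 | v > 1)) {
      stop_validation(comp, " must lie in [0,1]")
    }
  }
  if (any(!is.finite(CS) | CS < 0)) stop_validation("CS must be non-negative")
  pB * CS * pNS * sN
}

#' One-step expected population projection
#'
#' Deterministic expectation of the female-based projection: yearlings next
#' year are locally produced recruits (female share 0.5) plus yearling
#' immigrants; adults are survivors of both age classes plus adult immigrants.
#'
#' @param N_Y,N_A Current yearling/adult female abundance (non-negative).
#' @param rates Named list or vector with `F_Y`, `F_A` (fecundities, see
#'   [fecundity()]), `sJ` and `sA`.
#' @param imm_next Length-2 vector `c(immY, immA)` of immigrants arriving
#'   before the next census.
#' @return Named numeric `c(N_Y, N_A)` expected next-year abundances.
#' @export
project_expectation <- function(N_Y, N_A, rates, imm_next = c(0, 0)) {
  if (any(imm_next < 0)) stop_validation("immigrant counts must be non-negative")
  if (N_Y < 0 || N_A < 0) stop_validation("abundances must be non-negative")
  r <- as.list(rates)
  nY <- 0.5 * r$F_Y * r$sJ * N_Y + 0.5 * r$F_A * r$sJ * N_A + imm_next[1]
  nA <- r$sA * (N_Y + N_A) + imm_next[2]
  c(N_Y = nY, N_A = nA)
}

#' Realized annual population growth rates
#'
#' @param Ntot Numeric vector of total female abundances by year.
#' @return Vector of length `length(Ntot) - 1` with `lambda[t] =
#'   Ntot[t+1]/Ntot[t]`; `NA` where the denominator is zero.
#' @export
realized_growth <- function(Ntot) {
  if (length(Ntot) < 2) stop_validation("need at least two years of counts")
  lam <- Ntot[-1] / Ntot[-length(Ntot)]
  lam[Ntot[-length(Ntot)] == 0] <- NA_real_
  lam
}

#' Annual growth rate from per-year demographic components
#'
#' Writes the annual growth rate of the two-age-class model as
#' \deqn{\lambda = n_Y \cdot 0.5 F_Y s_J + (1 - n_Y) \cdot 0.5 F_A s_J + s_A
#'   + \omega_Y + \omega_A}
#' with fecundities \eqn{F_a = pB_a \, CS_a \, pNS \, sN_a}. When every
#' component is the realized per-capita value of a simulated trajectory (see
#' [realized_theta()]), this reproduces the realized growth ratio exactly.
#'
#' @param theta Named vector with the components of [theta_names()].
#' @return Scalar annual growth rate.
#' @export
lambda_decomposed <- function(theta) {
  theta <- .check_theta(theta)
  F_Y <- theta["pB_Y"] * theta["CS_Y"] * theta["pNS"] * theta["sN_Y"]
  F_A <- theta["pB_A"] * theta["CS_A"] * theta["pNS"] * theta["sN_A"]
  unname(theta["n_Y"] * 0.5 * F_Y * theta["sJ"] +
         (1 - theta["n_Y"]) * 0.5 * F_A * theta["sJ"] +
         theta["sA"] + theta["omega_Y"] + theta["omega_A"])
}

#' Expected number of breeding females and breeding fraction
#'
#' @param N Length-2 vector `c(yearling, adult)` abundances.
#' @param pB Length-2 vector of age-specific breeding probabilities.
#' @return List with `breeders` (expected breeding females) and `fraction`
#'   (breeders / total, `NA` when the population is empty).
#' @export
breeding_population <- function(N, pB) {
  if (any(N < 0)) stop_validation("abundances must be non-negative")
  if (any(pB < 0 | pB > 1)) stop_validation("pB must lie in [0,1]")
  B <- sum(N * pB)
  Ntot <- sum(N)
  list(breeders = B, fraction = if (Ntot > 0) B / Ntot else NA_real_)
}

#' Container for age- and year-indexed vital rates
#'
#' @param pB,CS,sN 2 x T matrices (rows `yearling`, `adult`).
#' @param pNS,sJ,sA Length-T vectors.
#' @return An object of class `vital_rate_series`.
#' @export
vital_rate_series <- function(pB, CS, pNS, sN, sJ, sA) {
  pB <- .as_age_matrix(pB); CS <- .as_age_matrix(CS); sN <- .as_age_matrix(sN)
  T <- ncol(pB)
  lens <- c(ncol(CS), ncol(sN), length(pNS), length(sJ), length(sA))
  if (any(lens != T)) stop_validation("vital rate arrays must share one year axis")
  for (p in list(pB, pNS, sN, sJ, sA)) {
    if (any(p < 0 | p > 1)) stop_validation("probabilities must lie in [0,1]")
  }
  if (any(CS < 0 | CS > 20)) stop_validation("clutch sizes must lie in [0,20]")
  structure(list(pB = pB, CS = CS, pNS = pNS, sN = sN, sJ = sJ, sA = sA,
                 n_years = T),
            class = "vital_rate_series")
}

.as_age_matrix <- function(x) {
  if (is.null(dim(x))) x <- rbind(x, x)
  x <- as.matrix(x)
  if (nrow(x) != 2) stop_validation("age-structured arrays need 2 rows")
  rownames(x) <- AGE_CLASSES
  x
}

#' Stochastic forward projection of the female population
#'
#' Simulates demographic stochasticity through the whole reproductive chain:
#' breeders are Binomial draws from each age class, nests escape complete
#' failure as a Binomial thinning, eggs are Poisson around successful-nest
#' clutch totals, fledglings Binomial per egg, the female share Binomial(0.5),
#' recruits Binomial with juvenile survival, adult survivors Binomial over the
#' whole population, and immigrants Poisson around their expected counts.
#'
#' @param rates A [vital_rate_series()] with T years of rates.
#' @param imm_expected 2 x T matrix of expected immigrant counts (rows
#'   yearling/adult); column t are arrivals before the census of year t+1.
#' @param init Length-2 vector `c(N_Y, N_A)` at the first census.
#' @param reps Number of replicate trajectories.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `ipm_projection`: abundance matrices `N_Y`,
#'   `N_A` (reps x T+1) and per-step bookkeeping of every stochastic stage,
#'   from which realized per-capita rates can be recovered ([realized_theta()]).
#' @export
stochastic_project <- function(rates, imm_expected, init, reps = 1,
                               seed = NULL) {
  stopifnot(inherits(rates, "vital_rate_series"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  T <- rates$n_years
  imm_expected <- .as_age_matrix(imm_expected)
  if (ncol(imm_expected) != T) stop_validation("imm_expected needs T columns")
  if (any(imm_expected < 0)) stop_validation("immigrant expectations must be >= 0")
  N_Y <- matrix(0L, reps, T + 1); N_A <- matrix(0L, reps, T + 1)
  N_Y[, 1] <- init[1]; N_A[, 1] <- init[2]
  keep <- c("B_Y", "B_A", "S_Y", "S_A", "E_Y", "E_A", "Fl_Y", "Fl_A",
            "Fem", "recruits", "survA", "ImmY", "ImmA")
  book <- lapply(keep, function(k) matrix(0L, reps, T))
  names(book) <- keep
  for (t in seq_len(T)) {
    B_Y <- rbinom(reps, N_Y[, t], rates$pB["yearling", t])
    B_A <- rbinom(reps, N_A[, t], rates$pB["adult", t])
    S_Y <- rbinom(reps, B_Y, rates$pNS[t])
    S_A <- rbinom(reps, B_A, rates$pNS[t])
    E_Y <- rpois(reps, S_Y * rates$CS["yearling", t])
    E_A <- rpois(reps, S_A * rates$CS["adult", t])
    Fl_Y <- rbinom(reps, E_Y, rates$sN["yearling", t])
    Fl_A <- rbinom(reps, E_A, rates$sN["adult", t])
    Fem <- rbinom(reps, Fl_Y + Fl_A, 0.5)
    recruits <- rbinom(reps, Fem, rates$sJ[t])
    survA <- rbinom(reps, N_Y[, t] + N_A[, t], rates$sA[t])
    ImmY <- rpois(reps, imm_expected["yearling", t])
    ImmA <- rpois(reps, imm_expected["adult", t])
    N_Y[, t + 1] <- recruits + ImmY
    N_A[, t + 1] <- survA + ImmA
    for (k in keep) book[[k]][, t] <- get(k)
  }
  structure(c(list(N_Y = N_Y, N_A = N_A, n_years = T, reps = reps), book),
            class = "ipm_projection")
}

#' Realized per-capita demographic components of a simulated trajectory
#'
#' Recovers, for one replicate of a [stochastic_project()] run, the per-year
#' parameter vector whose [lambda_decomposed()] value equals the realized
#' growth ratio exactly. Stage ratios define the realized rates. Two
#' components absorb pooled draws so the identity is exact: juvenile survival
#' takes up the realized sex-ratio draw (recruits / (0.5 fledglings)), and
#' realized clutch size is eggs per breeder divided by the pooled nest-success
#' ratio (nest failure is drawn per age class but reported as one pNS).
#' Ratios with zero denominator are set to 0 (their term contributes nothing).
#'
#' @param proj An `ipm_projection`.
#' @param rep Which replicate to extract.
#' @return 12 x T matrix, rows ordered as [theta_names()].
#' @export
realized_theta <- function(proj, rep = 1) {
  stopifnot(inherits(proj, "ipm_projection"))
  T <- proj$n_years
  g <- function(k) proj[[k]][rep, seq_len(T)]
  NY <- proj$N_Y[rep, seq_len(T)]; NA_ <- proj$N_A[rep, seq_len(T)]
  Ntot <- NY + NA_
  rat <- function(num, den) ifelse(den > 0, num / den, 0)
  Fl_tot <- g("Fl_Y") + g("Fl_A")
  pNS_hat <- rat(g("S_Y") + g("S_A"), g("B_Y") + g("B_A"))
  theta <- rbind(
    pB_Y = rat(g("B_Y"), NY),
    pB_A = rat(g("B_A"), NA_),
    CS_Y = rat(g("E_Y"), g("B_Y") * pNS_hat),
    CS_A = rat(g("E_A"), g("B_A") * pNS_hat),
    pNS = pNS_hat,
    sN_Y = rat(g("Fl_Y"), g("E_Y")),
    sN_A = rat(g("Fl_A"), g("E_A")),
    sJ = rat(g("recruits"), 0.5 * Fl_tot),
    sA = rat(g("survA"), Ntot),
    omega_Y = rat(g("ImmY"), Ntot),
    omega_A = rat(g("ImmA"), Ntot),
    n_Y = rat(NY, Ntot))
  theta
}

#' Pairwise covariation of year-by-year log population changes
#'
#' @param Ntot_list Named list of abundance series (possibly different
#'   lengths; series are aligned from their first year unless they carry a
#'   `years` attribute or names).
#' @param min_overlap Minimum overlapping year-steps required for a cell.
#' @return Symmetric correlation matrix of the log growth ratios; cells with
#'   fewer than `min_overlap` overlapping steps are `NA`.
#' @export
growth_covariation <- function(Ntot_list, min_overlap = 3) {
  if (length(Ntot_list) < 2) stop_validation("need at least two populations")
  dl <- lapply(Ntot_list, function(x) {
    yrs <- attr(x, "years")
    if (is.null(yrs) && !is.null(names(x))) yrs <- as.numeric(names(x))
    if (is.null(yrs)) yrs <- seq_along(x)
    d <- diff(log(as.numeric(x)))
    d[!is.finite(d)] <- NA
    setNames(d, yrs[-length(yrs)])
  })
  all_years <- sort(unique(unlist(lapply(dl, names))))
  M <- sapply(dl, function(d) d[match(all_years, names(d))])
  k <- length(dl)
  R <- diag(1, k); dimnames(R) <- list(names(Ntot_list), names(Ntot_list))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- complete.cases(M[, c(i, j)])
    R[i, j] <- R[j, i] <-
      if (sum(ok) >= min_overlap) cor(M[ok, i], M[ok, j]) else NA_real_
  }
  R
}

#' Monotonic population trend
#'
#' Spearman rank correlation of abundance against year, with mid-ranks for
#' ties; a constant series has no trend and returns 0.
#'
#' @param Ntot Abundance series (length >= 3).
#' @return Trend coefficient in `[-1, 1]`.
#' @export
population_trend <- function(Ntot) {
  if (length(Ntot) < 3) stop_validation("need at least three years")
  if (sd(Ntot) == 0) return(0)
  cor(rank(Ntot), rank(seq_along(Ntot)))
}
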