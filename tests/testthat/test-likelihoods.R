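test_that("linear predictor applies link, covariates and year effects", {
  expect_equal(linear_predictor(list(link = "logit", intercept = 0)), 0.5)
  expect_equal(linear_predictor(list(link = "log", intercept = log(6.5))),
               6.5)
  expect_equal(linear_predictor(list(link = "logit", intercept = 0,
                                     beta_rain = -1),
                                covariates = list(rain = 1)),
               plogis(-1), tolerance = 1e-6)
  expect_equal(plogis(-1), 0.26894, tolerance = 1e-4)
  m <- list(link = "logit", intercept = c(yearling = 0, adult = 1),
            eps = c(0.5, -0.5))
  expect_equal(linear_predictor(m, "adult", 2), plogis(0.5))
  expect_error(linear_predictor(list(link = "logit", intercept = 0,
                                     beta_rain = -1),
                                covariates = list()),
               "missing 'rain'")
})

test_that("CJS hand-computed histories match", {
  T <- 3
  pB <- matrix(0.4, 2, T)   # with pCapB = 1, p = 0.4
  pCapB <- rep(1, T)
  sJ <- rep(0.2, T); sA <- rep(0.5, T)
  h101 <- structure(list(individual = 1, ring_age = "adult", first_year = 1,
                         det = list(c(1L, 0L, 1L)), years = 1:3),
                    class = "capture_histories")
  expect_equal(cjs_loglik(h101, sJ, sA, pB, pCapB), log(0.5 * 0.6 * 0.5 * 0.4))
  h100 <- h101
  h100$det <- list(c(1L, 0L, 0L))
  expect_equal(cjs_loglik(h100, sJ, sA, pB, pCapB),
               log(0.5 + 0.5 * 0.6 * (0.5 + 0.5 * 0.6)))
  expect_equal(cjs_loglik(structure(list(individual = numeric(),
                                         ring_age = character(),
                                         first_year = numeric(), det = list(),
                                         years = 1:3),
                                    class = "capture_histories"),
                          sJ, sA, pB, pCapB), 0)
  expect_error(cjs_loglik(h101, rep(1.2, T), sA, pB, pCapB), "\\[0,1\\]")
})

test_that("CJS equals exhaustive enumeration and the m-array form", {
  for (k in 1:10) {
    T <- sample(3:6, 1)
    h <- random_histories(T, n = 15, seed = 100 + k)
    r <- random_cjs_rates(T, seed = 200 + k)
    ll <- cjs_loglik(h, r$sJ, r$sA, r$pB, r$pCapB)
    expect_equal(ll, enum_cjs_loglik(h, r$sJ, r$sA, r$pB, r$pCapB),
                 tolerance = 1e-10)
    expect_equal(ll, cjs_marray_loglik(build_marray(h), r$sJ, r$sA, r$pB,
                                       r$pCapB),
                 tolerance = 1e-8)
  }
})

test_that("clutch likelihood is the Poisson pmf and additive", {
  CS <- matrix(6, 2, 1)
  rec <- data.frame(age = "adult", year = 1, clutch = 6)
  expect_equal(clutch_loglik(rec, CS), 6 * log(6) - 6 - lfactorial(6))
  guard <- clutch_loglik(rec, matrix(0, 2, 1))  # finite guard at CS -> 0
  expect_lt(guard, -1e6)
  expect_true(is.finite(guard))
  set.seed(14)
  recs <- data.frame(age = sample(c("yearling", "adult"), 20, TRUE),
                     year = sample(3, 20, TRUE),
                     clutch = rpois(20, 6) + 1)
  CS3 <- matrix(runif(6, 4, 8), 2, 3)
  expect_equal(clutch_loglik(recs, CS3),
               sum(sapply(1:20, function(i)
                 clutch_loglik(recs[i, ], CS3))))
  expect_error(clutch_loglik(data.frame(age = "unknown", year = 1,
                                        clutch = 5), CS), "known")
})

test_that("nest fate mixes complete failure and per-egg survival", {
  rec <- data.frame(age = "adult", year = 1, clutch = 6, fledged = 6)
  expect_equal(nest_fate_loglik(rec, pNS = 1, sN = matrix(1, 2, 1)), 0)
  rec0 <- data.frame(age = "adult", year = 1, clutch = 1, fledged = 0)
  expect_equal(nest_fate_loglik(rec0, pNS = 0.8, sN = matrix(0.5, 2, 1)),
               log(0.2 + 0.8 * 0.5))
  expect_error(nest_fate_loglik(data.frame(age = "adult", year = 1,
                                           clutch = 4, fledged = 5),
                                0.8, matrix(.5, 2, 1)), "exceed")
})

test_that("nest fate MLE recovers generating values on simulated nests", {
  set.seed(15)
  n <- 4000; pNS0 <- 0.8; sN0 <- 0.85
  clutch <- rpois(n, 6) + 1
  ok <- rbinom(n, 1, pNS0)
  fl <- ifelse(ok == 1, rbinom(n, clutch, sN0), 0L)
  recs <- data.frame(age = "adult", year = 1, clutch = clutch, fledged = fl)
  nll <- function(p) -nest_fate_loglik(recs, p[1], matrix(p[2], 2, 1))
  est <- optim(c(0.7, 0.7), nll, method = "L-BFGS-B",
               lower = c(.01, .01), upper = c(.999, .999))$par
  expect_lt(abs(est[1] - pNS0), 0.03)
  expect_lt(abs(est[2] - sN0), 0.02)
})

test_that("count and state likelihoods follow their kernels", {
  T <- 2
  rates <- vital_rate_series(pB = matrix(1, 2, T), CS = matrix(5, 2, T),
                             pNS = rep(1, T), sN = matrix(1, 2, T),
                             sJ = rep(0.2, T), sA = rep(0.5, T))
  N <- matrix(c(4, 6, 5, 5), 2)
  counts <- data.frame(first_clutches = c(10, 10), eggs = c(50, 50),
                       fledglings = c(50, 50), newly_ringed = c(0, 3))
  Omega <- matrix(c(NA, NA, 2, 4), 2)
  ll <- counts_loglik(counts, N, rates, Omega, pCapB = c(1, 1))
  expect_equal(ll, dpois(10, 10, log = TRUE) * 2 +
                 dpois(50, 50, log = TRUE) * 4 +
                 dpois(3, 6, log = TRUE))
  # observed 0 with expectation 0 contributes 0
  expect_equal(counts_loglik(data.frame(first_clutches = 0, eggs = 0,
                                        fledglings = 0, newly_ringed = 0),
                             matrix(0, 2, 1),
                             vital_rate_series(matrix(.5, 2, 1),
                                               matrix(5, 2, 1), 1,
                                               matrix(.9, 2, 1), .1, .5),
                             matrix(0, 2, 1), 1), 0)
  imm <- matrix(c(0, 0, 1, 2), 2)
  ll_st <- state_transition_loglik(N, imm, rates, Omega)
  mu_rec <- 0.5 * 0.2 * sum(N[, 1] * 5)
  expect_equal(ll_st, dpois(5 - 1, mu_rec, log = TRUE) +
                 dbinom(5 - 2, 10, 0.5, log = TRUE) +
                 dpois(1, 2, log = TRUE) + dpois(2, 4, log = TRUE))
  # survivors exceeding previous total
  N_bad <- N; N_bad[2, 2] <- 20
  expect_identical(state_transition_loglik(N_bad, imm, rates, Omega), -Inf)
  # zero rates: only the all-zero successor has finite likelihood
  rates0 <- vital_rate_series(matrix(0, 2, T), matrix(0, 2, T), rep(0, T),
                              matrix(0, 2, T), rep(0, T), rep(0, T))
  expect_identical(state_transition_loglik(N, imm, rates0,
                                           matrix(0, 2, T)), -Inf)
  N0 <- matrix(c(4, 6, 0, 0), 2)
  expect_equal(state_transition_loglik(N0, matrix(0, 2, T), rates0,
                                       matrix(0, 2, T)), 0)
})

test_that("the sampler's joint density matches the R likelihood components", {
  d <- tiny_data()
  pr <- nestipm:::.resolve_priors(default_priors(), d)
  sdl <- nestipm:::.sampler_data(d, pr,
                                 c("cjs", "clutch", "nestfate", "counts",
                                   "state"))
  T <- d$T
  for (k in 1:3) {
    init <- nestipm:::.init_state(sdl, pr, 40 + k)
    cpp <- nestipm:::ipm_logpost_cpp(sdl, init)
    p <- setNames(init, nestipm:::.param_names(T))
    eps <- function(r) p[sprintf("eps_%s[%d]", r, 1:T)]
    z <- function(x) ifelse(is.na(x), 0, x)
    cv <- d$covariates
    pB <- rbind(plogis(qlogis(p["pB_Y"]) + eps("pB")),
                plogis(qlogis(p["pB_A"]) + eps("pB")))
    CS <- rbind(exp(log(p["CS_Y"]) + eps("CS")),
                exp(log(p["CS_A"]) + eps("CS")))
    pNS <- plogis(qlogis(p["pNS"]) + p["beta_rain_pNS"] * z(cv$rain_ph) +
                    p["beta_temp_pNS"] * z(cv$temp_ph) + eps("pNS"))
    sN <- rbind(plogis(qlogis(p["sN_Y"]) + p["beta_rain_sN"] * z(cv$rain_ph) +
                         p["beta_temp_sN"] * z(cv$temp_ph) + eps("sN")),
                plogis(qlogis(p["sN_A"]) + p["beta_rain_sN"] * z(cv$rain_ph) +
                         p["beta_temp_sN"] * z(cv$temp_ph) + eps("sN")))
    sJ <- plogis(qlogis(p["sJ"]) + p["beta_rain_sJ"] * z(cv$rain_pf) +
                   eps("sJ"))
    sA <- plogis(qlogis(p["sA"]) + eps("sA"))
    rates <- vital_rate_series(pB, CS, pNS, sN, sJ, sA)
    expect_equal(cpp$cjs, cjs_loglik(d$captures, sJ, sA, pB, sdl$pCapB),
                 tolerance = 1e-8)
    expect_equal(cpp$clutch,
                 clutch_loglik(d$repro[, c("age", "year", "clutch")], CS),
                 tolerance = 1e-8)
    expect_equal(cpp$nest, nest_fate_loglik(d$repro, pNS, sN),
                 tolerance = 1e-8)
    N <- rbind(c(p["N_Y[1]"], p[sprintf("localY[%d]", 2:T)] +
                   p[sprintf("ImmY[%d]", 2:T)]),
               c(p["N_A[1]"], p[sprintf("survA[%d]", 2:T)] +
                   p[sprintf("ImmA[%d]", 2:T)]))
    Om <- c(NA, p[sprintf("Omega_tot[%d]", 2:T)])
    Omega <- rbind(p["q_imm"] * Om, (1 - p["q_imm"]) * Om)
    imm <- rbind(c(NA, p[sprintf("ImmY[%d]", 2:T)]),
                 c(NA, p[sprintf("ImmA[%d]", 2:T)]))
    expect_equal(cpp$counts,
                 counts_loglik(d$counts, N, rates, Omega, sdl$pCapB),
                 tolerance = 1e-8)
    expect_equal(cpp$state, state_transition_loglik(N, imm, rates, Omega),
                 tolerance = 1e-8)
  }
})
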