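test_that("fecundity is the product of its reproductive components", {
  expect_equal(fecundity(1, 6, 1, 1), 6)
  expect_equal(fecundity(0, 6.5, 0.9, 0.9), 0)
  expect_equal(fecundity(0.9, 6.5, 0.8, 0.9), 4.212)
  expect_error(fecundity(1.2, 6, 1, 1), "pB")
  expect_error(fecundity(0.9, -1, 1, 1), "CS")
  expect_error(fecundity(0.9, 6, 1, 1.01), "sN")
})

test_that("one-step expectation equals the projection matrix product", {
  out <- project_expectation(100, 100, list(F_Y = 4, F_A = 4, sJ = 0.25,
                                            sA = 0.5), c(10, 20))
  expect_equal(unname(out), c(110, 120))
  expect_equal(unname(project_expectation(5, 9, list(F_Y = 3, F_A = 4,
                                                     sJ = 0, sA = 0))),
               c(0, 0))
  set.seed(11)
  for (k in 1:20) {
    N <- runif(2, 0, 300)
    r <- list(F_Y = runif(1, 0, 8), F_A = runif(1, 0, 8),
              sJ = runif(1), sA = runif(1))
    imm <- rpois(2, 15)
    A <- matrix(c(0.5 * r$F_Y * r$sJ, r$sA, 0.5 * r$F_A * r$sJ, r$sA), 2, 2)
    expect_equal(unname(project_expectation(N[1], N[2], r, imm)),
                 as.numeric(A %*% N + imm))
    # linearity in (N, Imm)
    a <- runif(1, 0, 3)
    expect_equal(unname(project_expectation(a * N[1], a * N[2], r, a * imm)),
                 a * unname(project_expectation(N[1], N[2], r, imm)))
  }
  expect_error(project_expectation(10, 10, list(F_Y = 1, F_A = 1, sJ = .1,
                                                sA = .5), c(-1, 0)),
               "non-negative")
})

test_that("realized growth is the ratio of successive totals", {
  expect_equal(realized_growth(c(100, 110, 99)), c(1.1, 0.9))
  expect_equal(realized_growth(rep(50, 5)), rep(1, 4))
  expect_equal(realized_growth(c(200, 230)), 1.15)
  expect_equal(realized_growth(c(10, 0, 5)), c(0, NA))
})

test_that("growth decomposition matches plug-in values and is monotone", {
  th <- setNames(rep(0, 12), theta_names())
  expect_equal(lambda_decomposed(th), 0)
  th2 <- th
  th2[c("pB_Y", "pB_A", "pNS", "sN_Y", "sN_A")] <- 1
  th2[c("CS_Y", "CS_A")] <- 1 / (0.5 * 0.25)  # so 0.5*F*sJ = 1 per age
  th2["sJ"] <- 0.25
  th2[c("sA", "omega_Y", "omega_A")] <- c(0.5, 0.05, 0.10)
  th2["n_Y"] <- 0.5
  expect_equal(lambda_decomposed(th2), 1.65)
  expect_error(lambda_decomposed(replace(random_theta(1), "n_Y", 1.4)), "n_Y")
  # monotone non-decreasing in every rate component; the yearling fraction
  # instead moves growth toward the more productive age class
  set.seed(21)
  for (k in 1:25) {
    th <- random_theta()
    i <- sample(11, 1)
    th_up <- th
    th_up[i] <- min(th[i] * 1.05, theta_upper_bounds[i])
    expect_gte(lambda_decomposed(th_up), lambda_decomposed(th))
    F_Y <- prod(th[c("pB_Y", "CS_Y", "pNS", "sN_Y")])
    F_A <- prod(th[c("pB_A", "CS_A", "pNS", "sN_A")])
    th_n <- replace(th, "n_Y", min(th["n_Y"] * 1.05, 1))
    dir <- lambda_decomposed(th_n) - lambda_decomposed(th)
    expect_gte(sign(dir) * sign(F_Y - F_A), 0)
  }
})

test_that("breeding population expectation and fraction", {
  bp <- breeding_population(c(50, 150), c(0.5, 0.9))
  expect_equal(bp$breeders, 160)
  expect_equal(bp$fraction, 0.8)
  expect_equal(breeding_population(c(10, 30), c(1, 1))$fraction, 1)
  expect_equal(breeding_population(c(10, 30), c(0, 0))$fraction, 0)
  expect_true(is.na(breeding_population(c(0, 0), c(0.5, 0.5))$fraction))
})

test_that("stochastic projection is seed-reproducible and dies without input", {
  T <- 5
  rates0 <- vital_rate_series(pB = matrix(0, 2, T), CS = matrix(0, 2, T),
                              pNS = rep(0, T), sN = matrix(0, 2, T),
                              sJ = rep(0, T), sA = rep(0, T))
  pr <- stochastic_project(rates0, matrix(0, 2, T), c(50, 50), reps = 20,
                           seed = 1)
  expect_true(all(pr$N_Y[, -1] == 0) && all(pr$N_A[, -1] == 0))
  tr <- tiny_truth()
  rates <- vital_rate_series(
    pB = matrix(tr$mu[c("pB_Y", "pB_A")], 2, T),
    CS = matrix(tr$mu[c("CS_Y", "CS_A")], 2, T),
    pNS = rep(tr$mu["pNS"], T),
    sN = matrix(tr$mu[c("sN_Y", "sN_A")], 2, T),
    sJ = rep(tr$mu["sJ"], T), sA = rep(tr$mu["sA"], T))
  imm <- matrix(c(5, 20), 2, T)
  p1 <- stochastic_project(rates, imm, c(40, 80), reps = 50, seed = 42)
  p2 <- stochastic_project(rates, imm, c(40, 80), reps = 50, seed = 42)
  expect_identical(p1, p2)
})

test_that("projection ensemble means converge to the deterministic expectation", {
  T <- 4
  tr <- tiny_truth()
  rates <- vital_rate_series(
    pB = matrix(tr$mu[c("pB_Y", "pB_A")], 2, T),
    CS = matrix(tr$mu[c("CS_Y", "CS_A")], 2, T),
    pNS = rep(tr$mu["pNS"], T),
    sN = matrix(tr$mu[c("sN_Y", "sN_A")], 2, T),
    sJ = rep(tr$mu["sJ"], T), sA = rep(tr$mu["sA"], T))
  imm <- matrix(c(5, 20), 2, T)
  reps <- 10000
  proj <- stochastic_project(rates, imm, c(40, 80), reps = reps, seed = 9)
  Fv <- c(fecundity(tr$mu["pB_Y"], tr$mu["CS_Y"], tr$mu["pNS"], tr$mu["sN_Y"]),
          fecundity(tr$mu["pB_A"], tr$mu["CS_A"], tr$mu["pNS"], tr$mu["sN_A"]))
  N <- c(40, 80)
  for (t in seq_len(T)) {
    N <- project_expectation(N[1], N[2],
                             list(F_Y = Fv[1], F_A = Fv[2],
                                  sJ = tr$mu[["sJ"]], sA = tr$mu[["sA"]]),
                             c(5, 20))
    for (a in 1:2) {
      sim_mean <- mean(list(proj$N_Y, proj$N_A)[[a]][, t + 1])
      sim_se <- sd(list(proj$N_Y, proj$N_A)[[a]][, t + 1]) / sqrt(reps)
      expect_lt(abs(sim_mean - N[a]), 3 * sim_se + 1e-9)
    }
  }
})

test_that("realized components reproduce realized growth exactly", {
  sim_truth <- tiny_truth()
  T <- 10
  rates <- vital_rate_series(
    pB = matrix(sim_truth$mu[c("pB_Y", "pB_A")], 2, T),
    CS = matrix(sim_truth$mu[c("CS_Y", "CS_A")], 2, T),
    pNS = rep(sim_truth$mu["pNS"], T),
    sN = matrix(sim_truth$mu[c("sN_Y", "sN_A")], 2, T),
    sJ = rep(sim_truth$mu["sJ"], T), sA = rep(sim_truth$mu["sA"], T))
  imm <- matrix(c(5, 20), 2, T)
  proj <- stochastic_project(rates, imm, c(40, 80), reps = 20, seed = 5)
  for (r in 1:20) {
    th <- realized_theta(proj, r)
    lam <- apply(th, 2, lambda_decomposed)
    Ntot <- proj$N_Y[r, ] + proj$N_A[r, ]
    expect_equal(lam, realized_growth(Ntot), tolerance = 1e-12)
  }
})

test_that("growth covariation handles identical, mirrored and short series", {
  x <- c(100, 120, 90, 140, 110, 130)
  R <- growth_covariation(list(a = x, b = x))
  expect_equal(R["a", "b"], 1)
  y <- exp(cumsum(-diff(log(x))))
  y <- c(1, y) * 100
  R2 <- growth_covariation(list(a = x, b = y))
  expect_equal(R2["a", "b"], -1)
  R3 <- growth_covariation(list(a = x[1:3], b = x[1:3]))
  expect_true(is.na(R3["a", "b"]))  # only 2 overlapping steps
  set.seed(30)
  long <- list(a = exp(cumsum(rnorm(1000, 0, .1))),
               b = exp(cumsum(rnorm(1000, 0, .1))))
  expect_lt(abs(growth_covariation(long)["a", "b"]), 0.1)
  expect_error(growth_covariation(list(a = x)), "two populations")
})

test_that("population trend matches a brute-force rank correlation", {
  expect_equal(population_trend(1:10), 1)
  expect_equal(population_trend(10:1), -1)
  expect_equal(population_trend(rep(7, 5)), 0)
  x <- c(5, 1, 4, 2, 3)
  rk <- rank(x); yr <- rank(1:5)
  oracle <- sum((rk - mean(rk)) * (yr - mean(yr))) /
    sqrt(sum((rk - mean(rk))^2) * sum((yr - mean(yr))^2))
  expect_equal(population_trend(x), oracle)
  expect_error(population_trend(c(1, 2)), "three years")
})
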