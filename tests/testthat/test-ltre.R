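test_that("analytic sensitivities match structure-free expectations", {
  th <- random_theta(50)
  s <- sensitivities(th)
  expect_equal(unname(s[c("sA", "omega_Y", "omega_A")]), c(1, 1, 1))
  th2 <- th
  th2["n_Y"] <- 0.5
  th2[c("pB_Y", "CS_Y", "sN_Y")] <- th2[c("pB_A", "CS_A", "sN_A")]
  F_A <- prod(th2[c("pB_A", "CS_A", "pNS", "sN_A")])
  s2 <- sensitivities(th2)
  expect_equal(unname(s2["sJ"]), unname(0.5 * F_A))
  expect_equal(unname(s2["n_Y"]), 0)   # symmetric age classes
  expect_error(sensitivities(replace(th, "pNS", 1.3)), "out of bounds")
})

test_that("sensitivities agree with central finite differences", {
  for (k in 1:20) {
    th <- random_theta(900 + k)
    s <- sensitivities(th)
    h <- 1e-6
    fd <- sapply(theta_names(), function(nm) {
      tp <- th; tm <- th
      tp[nm] <- tp[nm] + h; tm[nm] <- tm[nm] - h
      (lambda_decomposed(tp) - lambda_decomposed(tm)) / (2 * h)
    })
    expect_lt(max(abs(s - fd) / pmax(abs(fd), 1e-8)), 1e-6)
  }
})

test_that("random design: zero variance, single-rate variance, identity", {
  th <- random_theta(61)
  const <- matrix(th, 12, 8, dimnames = list(theta_names(), NULL))
  rd0 <- random_design(const)
  expect_true(all(rd0$contributions == 0))
  # only sA varies
  ths <- const
  set.seed(62)
  sa <- th["sA"] + scale(rnorm(8))[, 1] * sqrt(0.0025) * sqrt(7 / 8)
  # force exact sample variance 0.0025
  sa <- th["sA"] + (sa - mean(sa)) / sd(sa) * sqrt(0.0025)
  ths["sA", ] <- sa
  rd1 <- random_design(ths)
  expect_equal(unname(rd1$contributions["sA"]), 0.0025)
  expect_equal(unname(rd1$total), 0.0025)
  expect_true(all(rd1$contributions[setdiff(theta_names(), "sA")] == 0))
  # total approximates var(lambda) for small CV
  set.seed(63)
  n <- 200
  ser <- sapply(1:n, function(i)
    pmin(th * (1 + rnorm(12, 0, 0.05)), theta_upper_bounds))
  rownames(ser) <- theta_names()
  rd2 <- random_design(ser)
  v <- var(apply(ser, 2, lambda_decomposed))
  expect_lt(abs(rd2$total - v) / v, 0.10)
})

test_that("fixed design reproduces growth changes", {
  th <- random_theta(70)
  same <- cbind(th, th)
  rownames(same) <- theta_names()
  fx0 <- fixed_design(same)
  expect_true(all(fx0$contributions == 0))
  th2 <- th; th2["sA"] <- th["sA"] + 0.1
  fx1 <- fixed_design(cbind(th, th2))
  expect_equal(unname(fx1$contributions["sA", 1]), 0.1)
  expect_equal(unname(fx1$total), unname(fx1$delta_lambda))  # affine in sA
  set.seed(71)
  for (k in 1:10) {
    base <- random_theta()
    nxt <- pmin(base * runif(12, 0.95, 1.05), theta_upper_bounds)
    fx <- fixed_design(cbind(base, nxt))
    expect_lt(abs(fx$total - fx$delta_lambda) / abs(fx$delta_lambda), 0.05)
  }
})

test_that("real-time elasticities behave on constant series", {
  th <- random_theta(80)
  const <- matrix(th, 12, 6, dimnames = list(theta_names(), NULL))
  e <- realtime_elasticities(const)
  expect_true(all(e$e_sigma_direct == 0 & e$e_sigma_indirect == 0))
  lam <- lambda_decomposed(th)
  got <- e$e_mu_direct[e$parameter == "sA"]
  expect_lt(abs(got - th[["sA"]] / lam), 1e-3)
  # first-order stability under halving epsilon
  e2 <- realtime_elasticities(const, eps = 5e-5)
  expect_lt(max(abs(e2$e_mu_direct - e$e_mu_direct), na.rm = TRUE), 1e-3)
  # a parameter with zero period mean has no mu-elasticity
  z <- const; z["omega_Y", ] <- 0
  ez <- realtime_elasticities(z)
  expect_true(is.na(ez$e_mu_direct[ez$parameter == "omega_Y"]))
})

test_that("period design decomposes changes in geometric growth", {
  th <- random_theta(85)
  p1 <- matrix(th, 12, 8, dimnames = list(theta_names(), NULL))
  pd0 <- suppressWarnings(period_design(cbind(p1, p1), 1:8, 9:16))
  expect_true(all(abs(pd0$contributions) < 1e-8))
  expect_error(period_design(cbind(p1, p1), 1:8, 9:12), "same duration")
  # only the sA mean differs between two deterministic periods
  p2 <- p1; p2["sA", ] <- th["sA"] * 1.15
  pd1 <- suppressWarnings(period_design(cbind(p1, p2), 1:8, 9:16))
  expect_lt(abs(pd1$total - pd1$delta_log_lambda_g) /
              abs(pd1$delta_log_lambda_g), 0.05)
  # four-way split sums to the per-parameter contribution (bookkeeping)
  set.seed(86)
  pert <- function(m) {
    out <- m * (1 + matrix(rnorm(length(m), 0, 0.05), nrow(m)))
    pmin(out, theta_upper_bounds)
  }
  pp <- cbind(pert(p1), pert(p1 * 0.98))
  rownames(pp) <- theta_names()
  pd2 <- suppressWarnings(period_design(pp, 1:8, 9:16))
  expect_equal(rowSums(pd2$components, na.rm = TRUE),
               pd2$contributions)
})

test_that("parameters that never vary contribute exactly zero in all designs", {
  set.seed(90)
  th <- random_theta()
  ser <- matrix(th, 12, 12, dimnames = list(theta_names(), NULL))
  vary <- c("sA", "omega_A", "pNS")
  for (nm in vary) ser[nm, ] <- ser[nm, ] * (1 + rnorm(12, 0, 0.05))
  frozen <- setdiff(theta_names(), vary)
  expect_true(all(random_design(ser)$contributions[frozen] == 0))
  expect_true(all(fixed_design(ser)$contributions[frozen, ] == 0))
  pd <- suppressWarnings(period_design(ser, 1:6, 7:12))
  expect_true(all(pd$components[frozen, c("sigma_direct",
                                          "sigma_indirect")] == 0,
                  na.rm = TRUE))
})

test_that("posterior LTRE summarizes draws and handles degenerate input", {
  fit <- tiny_fit()
  expect_error(posterior_ltre(fit, "bayesian"), "random, fixed, period")
  res <- posterior_ltre(fit, "random", n_draws = 60)
  expect_equal(sort(unique(res$summary$group)),
               c("immigration", "reproduction", "structure", "survival"))
  expect_equal(nrow(res$draws), 60)
  expect_true(all(res$summary$lower95 <= res$summary$upper95))
  # group draws are sums of member parameter draws (linearity)
  imm_cols <- c("omega_Y", "omega_A")
  expect_equal(res$group_draws[, "immigration"],
               rowSums(res$draws[, imm_cols]))
  # degenerate posterior: identical draws -> zero-width intervals
  dg <- fit
  dg$chains <- lapply(fit$chains, function(m)
    fit$chains[[1]][rep(1, 5), , drop = FALSE])
  resd <- posterior_ltre(dg, "random", n_draws = 10)
  expect_equal(resd$summary$lower95, resd$summary$upper95)
  # fixed and period designs run end to end
  resf <- posterior_ltre(fit, "fixed", n_draws = 20)
  expect_equal(ncol(resf$draws), 12)
  T1 <- fit$data$T - 1
  resp <- suppressWarnings(posterior_ltre(fit, "period",
                                          period1 = 1:floor(T1 / 2),
                                          period2 = (T1 - floor(T1 / 2) +
                                                       1):T1,
                                          n_draws = 10))
  expect_equal(ncol(resp$draws), 12)
})
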