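test_that("prior bounds validate and prior draws respect type invariants", {
  pr <- default_priors()
  expect_equal(pr$beta_bound, 5)   # slope prior density is 0 at +/-6
  expect_error(default_priors(cs_max = -1), "positive")
  expect_error(default_priors(nonsense = 2), "unknown prior bound")
  set.seed(2)
  draws <- prior_predictive(default_priors(omega_max = 50), n = 1000)
  probs <- c("pB_Y", "pB_A", "pNS", "sN_Y", "sN_A", "sJ", "sA", "q_imm")
  expect_true(all(as.matrix(draws[probs]) >= 0 &
                    as.matrix(draws[probs]) <= 1))
  expect_true(all(draws$CS_A > 0 & draws$CS_A <= 12))
  expect_true(all(abs(draws$beta_rain_sJ) <= 5))
  expect_true(all(draws$sigma_sA >= 0 & draws$sigma_sA <= 3))
})

test_that("fit configuration enforces its invariants", {
  cfg <- fit_config(profile = "full")
  expect_equal(c(cfg$n_chains, cfg$n_iter, cfg$n_burnin, cfg$thin),
               c(4, 200000, 50000, 30))
  cfg2 <- fit_config(profile = "test")
  expect_equal(c(cfg2$n_chains, cfg2$n_iter, cfg2$n_burnin, cfg2$thin),
               c(3, 20000, 5000, 10))
  expect_error(fit_config(n_iter = 100, n_burnin = 200), "n_burnin")
  expect_error(fit_config(thin = 0), "thin")
})

test_that("Gelman-Rubin statistic follows its closed form", {
  set.seed(3)
  x <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "a"))
  expect_equal(unname(gelman_rubin(list(x, x))["a"]), sqrt(99 / 100))
  y1 <- matrix(rnorm(200, 0, 1), ncol = 1, dimnames = list(NULL, "a"))
  y2 <- matrix(rnorm(200, 20, 1), ncol = 1, dimnames = list(NULL, "a"))
  expect_gt(gelman_rubin(list(y1, y2))["a"], 3)
  set.seed(4)
  big <- lapply(1:3, function(i)
    matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "a")))
  r <- gelman_rubin(big)["a"]
  expect_gt(r, 0.99); expect_lt(r, 1.01)
  expect_error(gelman_rubin(list(x)), "2 chains")
  expect_error(gelman_rubin(list(x[1:5, , drop = FALSE],
                                 x[1:5, , drop = FALSE])), "10 retained")
})

test_that("the integrated fit is reproducible with a complete manifest", {
  fit <- tiny_fit()
  expect_s3_class(fit, "ipm_fit")
  d1 <- posterior_draws(fit)
  expect_true(all(is.finite(d1)))
  expect_equal(nrow(fit$manifest), ncol(fit$chains[[1]]))
  expect_setequal(fit$manifest$name, colnames(d1))
  # draws respect prior support
  expect_true(all(d1[, "sA"] > 0 & d1[, "sA"] < 1))
  expect_true(all(d1[, "CS_A"] > 0 & d1[, "CS_A"] <= fit$priors$cs_max))
  expect_true(all(abs(d1[, "beta_rain_sJ"]) <= fit$priors$beta_bound))
  expect_true(all(d1[, grep("Omega", colnames(d1))] >= 0))
  expect_true(all(d1[, grep("Imm|localY|survA|N_", colnames(d1))] >= 0))
  # determinism: same data + same base seed => identical draws
  fit2 <- fit_ipm(tiny_data(), tiny_config())
  expect_identical(fit$chains, fit2$chains)
  # a different seed moves the chains
  fit3 <- fit_ipm(tiny_data(), tiny_config(seed = 8))
  expect_false(identical(fit$chains[[1]], fit3$chains[[1]]))
})

test_that("posterior summaries and methods expose the fit", {
  fit <- tiny_fit()
  s <- summary(fit)
  expect_s3_class(s, "summary.ipm_fit")
  expect_true(all(c("pB_A", "sigma_sJ", "q_imm") %in% s$top$parameter))
  cf <- coef(fit)
  expect_length(cf, 21)
  expect_true(all(s$top$lower95 <= s$top$median &
                    s$top$median <= s$top$upper95))
  expect_output(print(fit), "Integrated population model fit")
  expect_silent(grDevices::pdf(NULL))
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("independent single-component fits recover their own rates", {
  d <- tiny_data()
  tr <- tiny_sim()$truth
  cfg <- fit_config(n_chains = 2, n_iter = 3000, n_burnin = 1000, thin = 5,
                    seed = 5, profile = "test")
  ind <- fit_independent(d, "clutch", cfg)
  expect_setequal(ind$manifest$name, tiny_fit()$manifest$name)
  cs <- ind$summary[ind$summary$parameter == "CS_A", ]
  expect_lt(abs(cs$median - tr$mu[["CS_A"]]), 0.4)
  cjs <- fit_independent(d, "survival", cfg)
  sa <- cjs$summary[cjs$summary$parameter == "sA", ]
  expect_lt(abs(sa$median - tr$mu[["sA"]]), 0.08)
  expect_true(sa$lower95 < tr$mu[["sA"]] + 0.1 &&
                sa$upper95 > tr$mu[["sA"]] - 0.1)
  expect_error(fit_independent(d, "counts"), "arg")
  empty <- d
  empty$captures <- structure(list(individual = character(),
                                   ring_age = character(),
                                   first_year = integer(), det = list(),
                                   years = d$years),
                              class = "capture_histories")
  expect_error(fit_independent(empty, "survival"), "no data rows")
})

test_that("posterior predictive table covers simulated observations", {
  fit <- tiny_fit()
  ppt <- posterior_predictive_table(fit, seed = 2)
  T <- fit$data$T
  expect_equal(nrow(ppt$table), 4 * T)  # years x streams
  expect_gte(ppt$coverage, 0.85)
  expect_lte(ppt$coverage, 1)
  # a constant series equal to the predictions is always covered
  ok <- !is.na(ppt$table$covered)
  expect_true(all(ppt$table$lower95[ok] <= ppt$table$upper95[ok]))
})

test_that("forward projections are seeded and die without survival", {
  fit <- tiny_fit()
  t1 <- forward_projection_check(fit, horizon = 10, reps = 300, seed = 3)
  t2 <- forward_projection_check(fit, horizon = 10, reps = 300, seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 11)
  expect_error(forward_projection_check(fit, horizon = 0), "horizon")
  med0 <- posterior_medians(fit)
  med0[c("pB_Y", "pB_A", "pNS", "sN_Y", "sN_A", "sJ", "sA")] <- 1e-12
  med0$Omega_tot <- 0
  dead <- nestipm:::.project_from_medians(med0, horizon = 3, reps = 50,
                                          seed = 1)
  expect_true(all(dead$upper95[-1] == 0))
  # replacement-level medians give a flat median trajectory
  med1 <- posterior_medians(fit)
  th <- c(pB_Y = med1$pB_Y, pB_A = med1$pB_A, CS_Y = med1$CS_Y,
          CS_A = med1$CS_A, pNS = med1$pNS, sN_Y = med1$sN_Y,
          sN_A = med1$sN_A, sJ = med1$sJ, sA = med1$sA, omega_Y = 0,
          omega_A = 0, n_Y = 0.35)
  lam_local <- lambda_decomposed(th)
  med1$q <- 0.2
  med1$Omega_tot <- (1 - lam_local) * sum(med1$last_state)  # top up to 1
  flat <- nestipm:::.project_from_medians(med1, horizon = 6, reps = 4000,
                                          seed = 2)
  expect_lt(abs(flat$median[7] - flat$median[1]) / flat$median[1], 0.15)
})
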