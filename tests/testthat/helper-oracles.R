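# Independent oracles and shared fixtures for the test suite.

# Brute-force CJS likelihood: enumerate the (latent) last-alive occasion of
# each individual and sum path probabilities directly. Independent of the
# chi-recursion / m-array implementations.
enum_cjs_loglik <- function(histories, sJ, sA, pB, pCapB) {
  pB <- rbind(pB)[rep(1:nrow(rbind(pB)), length.out = 2), , drop = FALSE]
  T <- ncol(pB)
  p <- pB * rep(pCapB, each = 2)
  year0 <- min(histories$years)
  total <- 0
  for (i in seq_along(histories$individual)) {
    det <- histories$det[[i]]
    r <- histories$first_year[i] - year0 + 1L
    juv <- histories$ring_age[i] == "nestling"
    occ <- seq.int(r, T)
    seen <- occ[det == 1]
    L <- max(seen)
    prob <- 0
    for (d in L:T) {            # d = last occasion alive
      pr <- 1
      if (d > r) for (t in r:(d - 1)) {
        phi <- if (juv && t == r) sJ[t] else sA[t]
        a <- if (juv && t + 1 == r + 1) 1L else 2L
        pr <- pr * phi *
          (if ((t + 1) %in% seen) p[a, t + 1] else 1 - p[a, t + 1])
      }
      if (d < T) {              # dies in interval d -> d+1
        phi <- if (juv && d == r) sJ[d] else sA[d]
        pr <- pr * (1 - phi)
      }
      prob <- prob + pr
    }
    total <- total + log(prob)
  }
  total
}

# random capture-history set on <= 6 occasions
random_histories <- function(T, n, seed) {
  set.seed(seed)
  ids <- seq_len(n)
  ring <- sample(c("nestling", "adult"), n, replace = TRUE)
  first <- sample(seq_len(T - 1), n, replace = TRUE)
  det <- lapply(seq_len(n), function(i) {
    v <- integer(T - first[i] + 1)
    v[1] <- 1L
    if (length(v) > 1) v[-1] <- rbinom(length(v) - 1, 1, 0.4)
    v
  })
  structure(list(individual = ids, ring_age = ring, first_year = first,
                 det = det, years = seq_len(T)),
            class = "capture_histories")
}

random_cjs_rates <- function(T, seed) {
  set.seed(seed)
  list(sJ = runif(T, 0.05, 0.6), sA = runif(T, 0.2, 0.9),
       pB = rbind(runif(T, 0.3, 0.95), runif(T, 0.3, 0.95)),
       pCapB = runif(T, 0.3, 1))
}

# random interior theta vector for sensitivity / LTRE checks
random_theta <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setNames(c(runif(1, .4, .9), runif(1, .5, .95), runif(1, 4, 7),
             runif(1, 4, 8), runif(1, .6, .95), runif(1, .7, .95),
             runif(1, .7, .95), runif(1, .05, .3), runif(1, .3, .6),
             runif(1, 0, .1), runif(1, .05, .4), runif(1, .2, .5)),
           theta_names())
}

theta_upper_bounds <- c(1, 1, 20, 20, 1, 1, 1, 1, 1, Inf, Inf, 1)

# small shared simulation + fit, built once per test run
.fixture_env <- new.env(parent = emptyenv())

tiny_truth <- function() {
  default_truth(n_years = 15, n_boxes = 60, init = c(25, 45),
                omega_mean = 25)
}

tiny_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(tiny_truth(), seed = 301)
  }
  .fixture_env$sim
}

tiny_data <- function() {
  if (is.null(.fixture_env$data)) .fixture_env$data <- as_ipm_data(tiny_sim())
  .fixture_env$data
}

tiny_config <- function(seed = 7) {
  fit_config(n_chains = 3, n_iter = 4000, n_burnin = 1500, thin = 5,
             seed = seed, profile = "test")
}

tiny_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    .fixture_env$fit <- fit_ipm(tiny_data(), tiny_config())
  }
  .fixture_env$fit
}
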