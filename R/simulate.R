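#' Generating parameter set for synthetic datasets
#'
#' Defaults emulate a mid-sized pied-flycatcher nestbox population: single
#' brood of six to seven eggs, adult apparent survival near 0.45, juvenile
#' apparent survival near 0.1, high nest success, substantial adult-biased
#' immigration keeping the population near stationarity, negative rainfall
#' effects on nest success, nestling survival and post-fledging juvenile
#' survival, and moderate random year variation on the link scale.
#'
#' @param n_years Number of study years.
#' @param n_boxes Number of nestboxes (box ids only; boxes are in excess).
#' @param init Initial `c(yearling, adult)` female abundances.
#' @param ... Named overrides of any truth component.
#' @return An object of class `ipm_truth`.
#' @export
default_truth <- function(n_years = 40, n_boxes = 150, init = c(45, 80), ...) {
  tr <- list(
    n_years = n_years, n_boxes = n_boxes, init = init,
    start_year = 1980,
    mu = c(pB_Y = 0.65, pB_A = 0.8, CS_Y = 6.0, CS_A = 6.5, pNS = 0.85,
           sN_Y = 0.87, sN_A = 0.9, sJ = 0.1, sA = 0.45),
    betas = c(beta_rain_pNS = -0.2, beta_temp_pNS = 0.1,
              beta_rain_sN = -0.2, beta_temp_sN = 0.1, beta_rain_sJ = -0.2),
    sigmas = c(pB = 0.2, CS = 0.05, pNS = 0.3, sN = 0.25, sJ = 0.3,
               sA = 0.2),
    q = 0.2, omega_mean = 45, sigma_omega = 0.3,
    pcap_beta = c(25.5, 4.5),     # yearly identification prob ~ Beta
    lay_mean = 125, lay_sd_year = 4, lay_sd_nest = 5)
  ov <- list(...)
  tr[names(ov)] <- ov
  structure(tr, class = "ipm_truth")
}

#' Named truth scenarios for LTRE power analysis
#'
#' Each scenario concentrates the among-year variance in one demographic
#' pathway. `"baseline"` uses the defaults; `"survival-driven"`,
#' `"immigration-driven"` and `"reproduction-driven"` switch off all other
#' sources of year variation; `"rain-sensitive"` makes weather the dominant
#' driver. Planted scenarios use a larger population so that demographic
#' sampling noise does not mask the planted pathway.
#'
#' @param name Scenario name.
#' @return An `ipm_truth` object.
#' @export
planted_scenarios <- function(name = c("baseline", "survival-driven",
                                       "immigration-driven",
                                       "reproduction-driven",
                                       "rain-sensitive")) {
  if (!name[1] %in% eval(formals(planted_scenarios)$name)) {
    stop_validation("unknown scenario '", name[1], "'; options: ",
                    paste(eval(formals(planted_scenarios)$name),
                          collapse = ", "))
  }
  name <- match.arg(name)
  z <- c(pB = 0, CS = 0, pNS = 0, sN = 0, sJ = 0, sA = 0)
  nb <- c(beta_rain_pNS = 0, beta_temp_pNS = 0, beta_rain_sN = 0,
          beta_temp_sN = 0, beta_rain_sJ = 0)
  switch(name,
    baseline = default_truth(),
    "survival-driven" = default_truth(
      init = c(110, 200), omega_mean = 110,
      sigmas = replace(z, c("sJ", "sA"), 0.5), betas = nb, sigma_omega = 0),
    "immigration-driven" = default_truth(
      init = c(110, 200), omega_mean = 110,
      sigmas = z, betas = nb, sigma_omega = 0.45),
    "reproduction-driven" = default_truth(
      init = c(110, 200), omega_mean = 8,
      mu = c(pB_Y = 0.65, pB_A = 0.8, CS_Y = 6.0, CS_A = 6.5, pNS = 0.85,
             sN_Y = 0.87, sN_A = 0.9, sJ = 0.3, sA = 0.45),
      sigmas = replace(z, c("pB", "pNS", "sN"), 0.6) |>
        replace("CS", 0.08),
      betas = nb, sigma_omega = 0),
    "rain-sensitive" = default_truth(
      sigmas = c(pB = 0.05, CS = 0.05, pNS = 0.05, sN = 0.05, sJ = 0.05,
                 sA = 0.05),
      betas = c(beta_rain_pNS = -0.6, beta_temp_pNS = 0.1,
                beta_rain_sN = -0.6, beta_temp_sN = 0.1,
                beta_rain_sJ = -0.6)))
}

#' Simulate daily May-August weather
#'
#' Minimum temperature follows a seasonal sinusoid plus AR(1) noise;
#' precipitation is Bernoulli-gamma (wet days with gamma-distributed
#' amounts).
#'
#' @param years Calendar years to simulate.
#' @param seed Optional seed.
#' @return Data frame `date, tmin_c, rain_mm` covering days-of-year 121-243.
#' @export
simulate_weather <- function(years, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  doy <- 121:243
  out <- do.call(rbind, lapply(years, function(y) {
    n <- length(doy)
    ar <- numeric(n)
    ar[1] <- rnorm(1, 0, 2)
    for (d in 2:n) ar[d] <- 0.6 * ar[d - 1] + rnorm(1, 0, 2 * sqrt(1 - 0.36))
    tmin <- 4 + 5 * sin(pi * (doy - 90) / 180) + ar
    wet <- rbinom(n, 1, 0.45)
    rain <- wet * rgamma(n, shape = 0.8, scale = 5)
    data.frame(date = as.Date(doy - 1, origin = sprintf("%d-01-01", y)),
               tmin_c = round(tmin, 2), rain_mm = round(rain, 2))
  }))
  rownames(out) <- NULL
  out
}

# long-run moments of the window-averaged covariates, used to standardize
# covariates inside the generator (the fitting side re-standardizes with
# sample moments). Computed once with an isolated RNG stream and cached.
.cov_ref_cache <- new.env(parent = emptyenv())
.cov_reference <- function() {
  if (!is.null(.cov_ref_cache$ref)) return(.cov_ref_cache$ref)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(913151)
  yrs <- 1601:1900
  w <- simulate_weather(yrs)
  vals <- sapply(yrs, function(y) {
    center <- round(rnorm(1, 125, 4) + 20)
    c(rain_ph = as.numeric(aggregate_covariate(w, y, c(center - 8, center + 8),
                                               "rain_mm")),
      temp_ph = as.numeric(aggregate_covariate(w, y, c(center - 8, center + 8),
                                               "tmin_c")),
      rain_pf = as.numeric(aggregate_covariate(w, y,
                                               c(center + 17, center + 24),
                                               "rain_mm")))
  })
  ref <- list(center = rowMeans(vals), scale = apply(vals, 1, sd))
  .cov_ref_cache$ref <- ref
  ref
}

#' Simulate a complete IPM dataset from known parameters
#'
#' Runs an individual-based simulation of the female population with the
#' model's own stochastic kernels (Bernoulli breeding, Poisson clutches,
#' Bernoulli whole-nest failure, Binomial egg survival and sex ratio,
#' Bernoulli annual survival, Poisson immigration), then generates the three
#' observation streams exactly as the model assumes them: nest records with
#' identification probability `pCapB`, capture histories for all
#' female-ringed nestlings and for adults detected at entry, and
#' newly-ringed-adult counts as `pCapB`-thinned immigrant arrivals.
#'
#' @param truth An `ipm_truth` from [default_truth()] or
#'   [planted_scenarios()].
#' @param seed Integer seed.
#' @return An object of class `ipm_simulation`: `nests`, `captures`
#'   (sightings data frame), `weather`, `years`, and a `truth` list holding
#'   the generating parameters plus realized abundances, stage counts and
#'   the realized per-year theta series.
#' @export
simulate_dataset <- function(truth = default_truth(), seed = 1) {
  stopifnot(inherits(truth, "ipm_truth"))
  ref <- .cov_reference()
  set.seed(seed)
  T <- truth$n_years
  years <- truth$start_year + seq_len(T) - 1
  weather <- simulate_weather(years)
  mu <- truth$mu; sg <- truth$sigmas; be <- truth$betas
  eps <- sapply(names(sg), function(r) rnorm(T, 0, sg[r]))
  om_eps <- rnorm(T, 0, truth$sigma_omega)
  Omega_tot <- truth$omega_mean * exp(om_eps - truth$sigma_omega^2 / 2)
  Omega_tot[1] <- NA
  pcap <- rbeta(T, truth$pcap_beta[1], truth$pcap_beta[2])
  mu_lay <- rnorm(T, truth$lay_mean, truth$lay_sd_year)

  # individual registry
  next_id <- 1L
  new_ids <- function(n) {
    ids <- seq.int(next_id, length.out = n)
    next_id <<- next_id + n
    ids
  }
  # alive females: id, age class (1/2), known_age, in_capture (has a history)
  alive <- data.frame(id = new_ids(truth$init[1] + truth$init[2]),
                      age = rep(c(1L, 2L), truth$init),
                      known_age = FALSE, in_capture = FALSE,
                      first_det = NA_integer_, ring_age = "adult",
                      stringsAsFactors = FALSE)
  nests <- vector("list", T)
  sightings <- vector("list", T)
  stage <- list()
  for (k in c("N_Y", "N_A", "B_Y", "B_A", "S_Y", "S_A", "E_Y", "E_A",
              "Fl_Y", "Fl_A", "Fem", "recruits", "survA", "ImmY", "ImmA",
              "arrivals", "nr")) stage[[k]] <- numeric(T)
  rate <- list()
  cov_rain_ph <- cov_temp_ph <- cov_rain_pf <- numeric(T)

  for (t in seq_len(T)) {
    stage$N_Y[t] <- sum(alive$age == 1L)
    stage$N_A[t] <- sum(alive$age == 2L)
    if (nrow(alive) == 0 && t <= ceiling(T / 2)) {
      warning("population went extinct in year ", t, "; dataset truncated")
      T <- t - 1L
      break
    }
    pB_t <- plogis(qlogis(mu[c("pB_Y", "pB_A")]) + eps[t, "pB"])
    CS_t <- exp(log(mu[c("CS_Y", "CS_A")]) + eps[t, "CS"])
    # nest phenology and clutches first; weather windows and the weather-
    # dependent rates follow from the realized phenology
    breeds <- rbinom(nrow(alive), 1, pB_t[alive$age]) == 1
    nb <- sum(breeds)
    fe <- round(rnorm(nb, mu_lay[t], truth$lay_sd_nest))
    cl <- pmax(rpois(nb, CS_t[alive$age[breeds]]), 1)
    hatch <- hatch_date(fe, cl)
    win_ph <- posthatch_window(hatch)
    win_pf <- postfledge_window(hatch)
    std <- function(raw, v) (raw - ref$center[v]) / ref$scale[v]
    cov_rain_ph[t] <- std(as.numeric(aggregate_covariate(weather, years[t],
                                                         win_ph, "rain_mm")),
                          "rain_ph")
    cov_temp_ph[t] <- std(as.numeric(aggregate_covariate(weather, years[t],
                                                         win_ph, "tmin_c")),
                          "temp_ph")
    cov_rain_pf[t] <- std(as.numeric(aggregate_covariate(weather, years[t],
                                                         win_pf, "rain_mm")),
                          "rain_pf")
    if (nb == 0) { cov_rain_ph[t] <- cov_temp_ph[t] <- cov_rain_pf[t] <- 0 }
    pNS_t <- plogis(qlogis(mu["pNS"]) + be["beta_rain_pNS"] * cov_rain_ph[t] +
                      be["beta_temp_pNS"] * cov_temp_ph[t] + eps[t, "pNS"])
    sN_t <- plogis(qlogis(mu[c("sN_Y", "sN_A")]) +
                     be["beta_rain_sN"] * cov_rain_ph[t] +
                     be["beta_temp_sN"] * cov_temp_ph[t] + eps[t, "sN"])
    sJ_t <- plogis(qlogis(mu["sJ"]) + be["beta_rain_sJ"] * cov_rain_pf[t] +
                     eps[t, "sJ"])
    sA_t <- plogis(qlogis(mu["sA"]) + eps[t, "sA"])
    rate$pB <- cbind(rate$pB, pB_t); rate$CS <- cbind(rate$CS, CS_t)
    rate$pNS <- c(rate$pNS, pNS_t); rate$sN <- cbind(rate$sN, sN_t)
    rate$sJ <- c(rate$sJ, sJ_t); rate$sA <- c(rate$sA, sA_t)

    ok <- rbinom(nb, 1, pNS_t) == 1
    mother_age <- alive$age[breeds]
    fl <- integer(nb)
    fl[ok] <- rbinom(sum(ok), cl[ok], sN_t[mother_age[ok]])
    ident <- rbinom(nb, 1, pcap[t]) == 1
    for (a in 1:2) {
      sel <- mother_age == a
      stage[[c("B_Y", "B_A")[a]]][t] <- sum(sel)
      stage[[c("S_Y", "S_A")[a]]][t] <- sum(sel & ok)
      stage[[c("E_Y", "E_A")[a]]][t] <- sum(cl[sel & ok])
      stage[[c("Fl_Y", "Fl_A")[a]]][t] <- sum(fl[sel & ok])
    }
    mothers <- alive[breeds, ]
    age_label <- ifelse(!ident, NA,
                 ifelse(mothers$known_age,
                        c("yearling", "adult")[mothers$age],
                 ifelse(!is.na(mothers$first_det) & mothers$first_det < t,
                        "adult", "unknown")))
    nests[[t]] <- data.frame(
      site = "SIM", year = years[t],
      box = sample.int(truth$n_boxes, nb, replace = nb > truth$n_boxes),
      first_egg_doy = fe, clutch = cl, fledged = fl,
      female_id = ifelse(ident, sprintf("F%06d", mothers$id), NA),
      female_age = ifelse(is.na(age_label), "unknown", age_label),
      replacement = FALSE, stringsAsFactors = FALSE)
    # detections: breeding + identified
    det_now <- mothers$id[ident & mothers$in_capture]
    newly_hist <- ident & !mothers$in_capture & t == 1L
    # initial birds enter the capture data only via year-1 identification;
    # immigrants enter at arrival (below)
    if (any(newly_hist)) {
      idx <- match(mothers$id[newly_hist], alive$id)
      alive$in_capture[idx] <- TRUE
      alive$first_det[idx] <- t
    }
    idx2 <- match(mothers$id[ident], alive$id)
    alive$first_det[idx2] <- pmin(alive$first_det[idx2], t, na.rm = TRUE)
    det_ids <- c(det_now, mothers$id[newly_hist])
    sightings[[t]] <- data.frame(id = det_ids,
                                 year = rep(t, length(det_ids)))
    # female fledglings: ringed as nestlings, capture history from year t
    fem_per_nest <- rbinom(nb, fl, 0.5)
    stage$Fem[t] <- sum(fem_per_nest)
    if (t < T) {
      juv_alive <- rbinom(stage$Fem[t], 1, sJ_t) == 1
      stage$recruits[t + 1] <- sum(juv_alive)
      surv <- rbinom(nrow(alive), 1, sA_t) == 1
      stage$survA[t + 1] <- sum(surv)
      arrivals <- rpois(1, Omega_tot[t + 1])
      immY <- rbinom(1, arrivals, truth$q)
      stage$arrivals[t + 1] <- arrivals
      stage$ImmY[t + 1] <- immY
      stage$ImmA[t + 1] <- arrivals - immY
      # assemble next year's population
      recruit_ids <- new_ids(stage$recruits[t + 1])
      juv_ring_ids <- c(recruit_ids, new_ids(stage$Fem[t] -
                                               stage$recruits[t + 1]))
      # every female nestling gets a history starting at ringing year t
      sightings[[t]] <- rbind(sightings[[t]],
                              data.frame(id = juv_ring_ids, year = NA)[0, ])
      juv_hist <- data.frame(id = juv_ring_ids,
                             ring_age = rep("nestling", length(juv_ring_ids)),
                             first_year = rep(t, length(juv_ring_ids)))
      attr(sightings[[t]], "juv_hist") <- juv_hist
      # the newly-ringed-adult count IS the entry detection of immigrants
      imm_det <- rbinom(arrivals, 1, pcap[t + 1]) == 1
      stage$nr[t + 1] <- sum(imm_det)
      imm_ids <- new_ids(arrivals)
      survivors <- alive[surv, ]
      survivors$age <- 2L
      imm <- data.frame(id = imm_ids,
                        age = c(rep(1L, immY), rep(2L, arrivals - immY)),
                        known_age = rep(FALSE, arrivals),
                        in_capture = imm_det,
                        first_det = ifelse(imm_det, t + 1L, NA_integer_),
                        ring_age = rep("adult", arrivals),
                        stringsAsFactors = FALSE)
      nrec <- length(recruit_ids)
      recruits_df <- data.frame(id = recruit_ids, age = rep(1L, nrec),
                                known_age = rep(TRUE, nrec),
                                in_capture = rep(TRUE, nrec),
                                first_det = rep(NA_integer_, nrec),
                                ring_age = rep("nestling", nrec),
                                stringsAsFactors = FALSE)
      alive <- rbind(survivors, recruits_df, imm)
      nd <- sum(imm_det)
      attr(sightings[[t]], "entry_det") <- data.frame(
        id = imm_ids[imm_det], ring_age = rep("adult", nd),
        first_year = rep(t + 1L, nd))
    }
  }
  years <- years[seq_len(T)]
  # assemble capture table: histories (first_year, ring_age) + sighting rows
  hist_rows <- list()
  seen_rows <- list()
  for (t in seq_len(T)) {
    s <- sightings[[t]]
    if (!is.null(attr(s, "juv_hist"))) hist_rows[[length(hist_rows) + 1]] <-
      attr(s, "juv_hist")
    if (!is.null(attr(s, "entry_det"))) {
      ed <- attr(s, "entry_det")
      if (nrow(ed)) hist_rows[[length(hist_rows) + 1]] <-
        data.frame(id = ed$id, ring_age = ed$ring_age,
                   first_year = ed$first_year)
    }
    if (nrow(s)) seen_rows[[length(seen_rows) + 1]] <-
      data.frame(id = s$id, year = s$year)
  }
  # year-1 adult histories were registered through newly_hist
  y1 <- do.call(rbind, seen_rows)
  hist_df <- do.call(rbind, hist_rows)
  # initial birds detected in year 1: their history record
  init_hist <- unique(y1$id[y1$year == 1 & !y1$id %in% hist_df$id])
  if (length(init_hist)) hist_df <- rbind(hist_df,
    data.frame(id = init_hist, ring_age = "adult", first_year = 1L))
  hist_df <- hist_df[!duplicated(hist_df$id), ]
  seen <- y1[!is.na(y1$year), ]
  seen <- merge(seen, hist_df, by = "id")
  seen <- seen[seen$year > seen$first_year, ]  # first capture is implied
  captures <- rbind(
    data.frame(individual = sprintf("F%06d", hist_df$id),
               ring_age = hist_df$ring_age,
               first_year = years[hist_df$first_year],
               year_seen = NA_integer_),
    data.frame(individual = sprintf("F%06d", seen$id),
               ring_age = seen$ring_age,
               first_year = years[seen$first_year],
               year_seen = years[seen$year]))
  captures <- captures[order(captures$individual, captures$year_seen), ]
  rownames(captures) <- NULL
  nests <- do.call(rbind, nests[seq_len(T)])
  rownames(nests) <- NULL

  truth_out <- c(truth, list(
    years = years, Omega_tot = Omega_tot[seq_len(T)],
    pCapB = pcap[seq_len(T)],
    covariates = data.frame(year = years, rain_ph = cov_rain_ph[seq_len(T)],
                            temp_ph = cov_temp_ph[seq_len(T)],
                            rain_pf = cov_rain_pf[seq_len(T)]),
    rates = rate, stage = lapply(stage, function(x) x[seq_len(T)]),
    eps = eps[seq_len(T), , drop = FALSE]))
  truth_out$realized_theta <- .realized_theta_from_stage(truth_out$stage)
  structure(list(nests = nests, captures = captures, weather = weather,
                 years = years, truth = truth_out),
            class = "ipm_simulation")
}

# realized per-year theta series (years 1..T-1) from stage counts; same
# conventions as realized_theta() so the growth decomposition is exact
.realized_theta_from_stage <- function(st) {
  T <- length(st$N_Y)
  idx <- seq_len(T - 1)
  rat <- function(num, den) ifelse(den > 0, num / den, 0)
  Ntot <- st$N_Y + st$N_A
  pNS_hat <- rat(st$S_Y + st$S_A, st$B_Y + st$B_A)
  Fl_tot <- st$Fl_Y + st$Fl_A
  th <- rbind(
    pB_Y = rat(st$B_Y, st$N_Y), pB_A = rat(st$B_A, st$N_A),
    CS_Y = rat(st$E_Y, st$B_Y * pNS_hat),
    CS_A = rat(st$E_A, st$B_A * pNS_hat),
    pNS = pNS_hat,
    sN_Y = rat(st$Fl_Y, st$E_Y), sN_A = rat(st$Fl_A, st$E_A),
    sJ = rat(c(st$recruits[-1], 0), 0.5 * Fl_tot),
    sA = rat(c(st$survA[-1], 0), Ntot),
    omega_Y = rat(c(st$ImmY[-1], 0), Ntot),
    omega_A = rat(c(st$ImmA[-1], 0), Ntot),
    n_Y = rat(st$N_Y, Ntot))
  th[, idx, drop = FALSE]
}

#' Write a simulated dataset to CSV files plus a truth manifest
#'
#' Emits `nests.csv`, `captures.csv`, `weather.csv` in the dialects the
#' readers expect, and `truth.json` with the generating parameters.
#'
#' @param sim An `ipm_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ipm_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nest_table(sim$nests, file.path(dir, "nests.csv"))
  utils::write.csv(sim$captures, file.path(dir, "captures.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(sim$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  tr <- sim$truth
  manifest <- list(
    n_years = tr$n_years, n_boxes = tr$n_boxes, init = tr$init,
    start_year = tr$start_year, mu = as.list(tr$mu),
    betas = as.list(tr$betas), sigmas = as.list(tr$sigmas), q = tr$q,
    omega_mean = tr$omega_mean, sigma_omega = tr$sigma_omega,
    Omega_tot = tr$Omega_tot, pCapB = tr$pCapB,
    Ntot = tr$stage$N_Y + tr$stage$N_A)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Load a simulated dataset directory into an [ipm_data()] bundle
#' @param dir Directory written by [write_simulation()].
#' @return An `ipm_data` object.
#' @export
read_simulation <- function(dir) {
  nests <- read_nest_table(file.path(dir, "nests.csv"))
  weather <- read_weather_table(file.path(dir, "weather.csv"))
  years <- sort(unique(nests$year))
  years <- seq(min(years), max(years))
  captures <- read_capture_table(file.path(dir, "captures.csv"), years)
  ipm_data(nests, captures, weather, years)
}

#' Convert an in-memory simulation straight to an [ipm_data()] bundle
#' @param sim An `ipm_simulation`.
#' @return An `ipm_data` object.
#' @export
as_ipm_data <- function(sim) {
  stopifnot(inherits(sim, "ipm_simulation"))
  ch <- capture_histories(
    data.frame(individual = sim$captures$individual,
               ring_age = sim$captures$ring_age,
               first_year = sim$captures$first_year,
               year_seen = sim$captures$year_seen), sim$years)
  ipm_data(sim$nests, ch, sim$weather, sim$years)
}
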