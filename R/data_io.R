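NEST_COLS <- c("site", "year", "box", "first_egg_doy", "clutch", "fledged",
               "female_id", "female_age", "replacement")

#' Read a nest-record table
#'
#' Expects a CSV with columns `site, year, box, first_egg_doy, clutch,
#' fledged, female_id, female_age, replacement`. Rows violating
#' `fledged <= clutch` are rejected and reported (attribute `"rejected"`,
#' carrying the offending row numbers).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of validated nest records (class `nest_table`).
#' @export
read_nest_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(NEST_COLS, names(df))
  if (length(missing_cols)) {
    stop_validation("nest table is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  df <- df[NEST_COLS]
  df$female_id <- as.character(df$female_id)
  df$female_id[df$female_id %in% c("", "NA")] <- NA_character_
  df$female_age <- as.character(df$female_age)
  df$female_age[is.na(df$female_age) | df$female_age == ""] <- "unknown"
  bad_age <- !df$female_age %in% c(AGE_CLASSES, "unknown")
  if (any(bad_age)) {
    stop_validation("invalid female_age at row(s): ",
                    paste(utils::head(which(bad_age), 5), collapse = ", "))
  }
  df$replacement <- as.logical(df$replacement)
  bad <- which(!is.na(df$fledged) & !is.na(df$clutch) & df$fledged > df$clutch)
  rejected <- df[bad, , drop = FALSE]
  if (length(bad)) {
    warning(sprintf("rejected %d nest row(s) with fledged > clutch: rows %s",
                    length(bad), paste(bad, collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  attr(df, "rejected") <- cbind(row = bad, rejected)
  class(df) <- c("nest_table", "data.frame")
  df
}

#' Write a nest-record table
#' @param nests A nest `data.frame` with the standard columns.
#' @param path Output CSV path.
#' @export
write_nest_table <- function(nests, path) {
  utils::write.csv(as.data.frame(nests)[NEST_COLS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read mark-recapture sightings and assemble capture histories
#'
#' Expects a long-format CSV `individual, ring_age, first_year, year_seen`
#' with one row per sighting (the first capture itself included or not; it is
#' implied). Duplicate sightings collapse to one detection.
#'
#' @param path Path to the CSV file.
#' @param years Study year range (integer vector); defaults to the span of
#'   the data.
#' @return Object of class `capture_histories`: per-individual ring age,
#'   first year, and 0/1 detection vectors from the first year to study end.
#' @export
read_capture_table <- function(path, years = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "ring_age", "first_year", "year_seen")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_validation("capture table is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  if (!all(df$ring_age %in% c("nestling", "adult"))) {
    stop_validation("ring_age must be 'nestling' or 'adult'")
  }
  if (any(df$year_seen < df$first_year, na.rm = TRUE)) {
    stop_validation("sighting before declared first year for individual(s): ",
                    paste(unique(df$individual[df$year_seen < df$first_year]),
                          collapse = ", "))
  }
  if (is.null(years)) {
    years <- seq(min(df$first_year), max(c(df$first_year, df$year_seen),
                                         na.rm = TRUE))
  }
  capture_histories(df, years)
}

#' Build capture histories from a sightings data frame
#' @param sightings Data frame with `individual, ring_age, first_year,
#'   year_seen` (one row per sighting; `year_seen` may be `NA` for
#'   never-resighted individuals).
#' @param years Study year range.
#' @return A `capture_histories` object.
#' @export
capture_histories <- function(sightings, years) {
  ids <- unique(sightings$individual)
  first <- sightings$first_year[match(ids, sightings$individual)]
  ring <- sightings$ring_age[match(ids, sightings$individual)]
  Tend <- max(years)
  det <- lapply(seq_along(ids), function(i) {
    span <- first[i]:Tend
    v <- integer(length(span))
    v[1] <- 1L
    seen <- sightings$year_seen[sightings$individual == ids[i]]
    seen <- unique(seen[!is.na(seen)])
    v[match(seen, span)] <- 1L
    v
  })
  structure(list(individual = ids, ring_age = ring, first_year = first,
                 det = det, years = years),
            class = "capture_histories")
}

#' Write capture histories back to the long sightings format
#' @param ch A `capture_histories` object.
#' @param path Output CSV path.
#' @export
write_capture_table <- function(ch, path) {
  rows <- do.call(rbind, lapply(seq_along(ch$individual), function(i) {
    span <- ch$first_year[i]:max(ch$years)
    seen <- span[ch$det[[i]] == 1][-1]  # first capture implied
    data.frame(individual = ch$individual[i], ring_age = ch$ring_age[i],
               first_year = ch$first_year[i],
               year_seen = if (length(seen)) seen else NA_integer_)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a daily weather table
#' @param path CSV with columns `date` (ISO), `tmin_c`, `rain_mm`.
#' @return Data frame with a `Date` column.
#' @export
read_weather_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "rain_mm")
  if (!all(need %in% names(df))) {
    stop_validation("weather table needs columns: ", paste(need, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_validation("unparsable dates in weather table")
  df
}

#' Hatch date from first-egg date and clutch size
#'
#' One egg is laid per day and incubation takes 14 days, so hatching is at
#' `first_egg + clutch + 14`. Missing first-egg dates propagate.
#'
#' @param first_egg Day-of-year of the first egg (may be `NA`).
#' @param clutch Clutch size (>= 1).
#' @return Day-of-year of hatching. Vectorized.
#' @export
hatch_date <- function(first_egg, clutch) {
  if (any(clutch < 1, na.rm = TRUE)) stop_validation("clutch must be >= 1")
  first_egg + clutch + 14
}

# 0.25 quantile with linear interpolation, rounded half-down to a whole day
.q25_day <- function(hatch) {
  q <- unname(quantile(hatch, 0.25, type = 7, na.rm = TRUE))
  as.integer(ceiling(q - 0.5))
}

#' Post-hatching covariate window
#'
#' The window covers 8 days either side of the 0.25 quantile of the year's
#' hatch dates (17 days total). The quantile uses linear interpolation
#' between order statistics and is rounded half-down to a whole day.
#'
#' @param hatch Vector of hatch dates (day-of-year) for one year.
#' @return Integer `c(start, end)`, inclusive; `c(NA, NA)` if no dates.
#' @export
posthatch_window <- function(hatch) {
  hatch <- hatch[!is.na(hatch)]
  if (!length(hatch)) return(c(start = NA_integer_, end = NA_integer_))
  c0 <- .q25_day(hatch)
  c(start = c0 - 8L, end = c0 + 8L)
}

#' Post-fledging covariate window
#'
#' Fledging is assumed at the window-centre hatch day + 16-day nestling
#' period + 1; the window spans 7 days from that date (8 calendar days,
#' fledging day included).
#'
#' @inheritParams posthatch_window
#' @return Integer `c(start, end)`, inclusive; `c(NA, NA)` if no dates.
#' @export
postfledge_window <- function(hatch) {
  hatch <- hatch[!is.na(hatch)]
  if (!length(hatch)) return(c(start = NA_integer_, end = NA_integer_))
  f <- .q25_day(hatch) + 17L
  c(start = f, end = f + 7L)
}

#' Mean of a daily weather variable over a within-year window
#'
#' @param env Weather data frame from [read_weather_table()].
#' @param year Calendar year.
#' @param window Integer `c(start, end)` day-of-year, inclusive.
#' @param variable `"tmin_c"` or `"rain_mm"`.
#' @return Mean over non-missing days (attribute `n_missing` reports exclusions);
#'   `NA` if the whole window is missing.
#' @export
aggregate_covariate <- function(env, year, window, variable = c("rain_mm", "tmin_c")) {
  variable <- match.arg(variable)
  if (anyNA(window)) return(NA_real_)
  doy <- as.integer(format(env$date, "%j"))
  yr <- as.integer(format(env$date, "%Y"))
  sel <- yr == year & doy >= window[1] & doy <= window[2]
  vals <- env[[variable]][sel]
  n_days <- window[2] - window[1] + 1L
  n_missing <- n_days - sum(!is.na(vals))
  if (all(is.na(vals)) || !length(vals)) return(structure(NA_real_, n_missing = n_days))
  structure(mean(vals, na.rm = TRUE), n_missing = n_missing)
}

#' z-standardize a covariate series
#'
#' Centres and scales with the sample mean and SD (denominator n - 1) over
#' non-missing entries; missing values stay missing. Standardizing an already
#' standardized series is a no-op.
#'
#' @param x Numeric vector (>= 2 non-missing values).
#' @return Standardized vector with attributes `center` and `scale`.
#' @export
zstandardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop_validation("need >= 2 non-missing values to standardize")
  s <- sd(x[ok])
  if (s == 0) stop_validation("constant covariate (SD = 0); drop it")
  m <- mean(x[ok])
  structure((x - m) / s, center = m, scale = s)
}

#' Proportion of nests with an identified breeding female, per year
#'
#' Approximates the probability that a breeding female is captured and
#' identified (the quantity that, multiplied by breeding probability, gives
#' the CJS recapture probability).
#'
#' @param nests Nest data frame.
#' @param years Year range to report (defaults to years present).
#' @return Named vector of proportions; `NA` for years with no nests.
#' @export
identified_proportion <- function(nests, years = sort(unique(nests$year))) {
  out <- sapply(years, function(y) {
    n <- sum(nests$year == y)
    if (n == 0) return(NA_real_)
    sum(nests$year == y & !is.na(nests$female_id)) / n
  })
  setNames(out, years)
}

#' Derive annual population-level count series
#'
#' First clutches approximate the number of breeding females; eggs and
#' fledglings are annual sums over all surveyed nests; newly ringed adult
#' females (the immigration proxy) are capture histories first marked as
#' adults in each year.
#'
#' @param nests Nest data frame.
#' @param captures A `capture_histories` object.
#' @param years Study years.
#' @return Data frame: `year, first_clutches, eggs, fledglings, newly_ringed,
#'   pCapB`.
#' @export
build_population_counts <- function(nests, captures, years) {
  pcap <- identified_proportion(nests, years)
  out <- data.frame(
    year = years,
    first_clutches = sapply(years, function(y)
      sum(nests$year == y & !nests$replacement)),
    eggs = sapply(years, function(y) sum(nests$clutch[nests$year == y])),
    fledglings = sapply(years, function(y) sum(nests$fledged[nests$year == y])),
    newly_ringed = sapply(years, function(y)
      sum(captures$ring_age == "adult" & captures$first_year == y)),
    pCapB = as.numeric(pcap))
  out
}

#' Per-year covariate windows from nest phenology
#'
#' @param nests Nest data frame (first-egg dates and clutch sizes).
#' @param years Study years.
#' @return List with integer matrices `posthatch` and `postfledge`
#'   (years x start/end); rows are `NA` where no hatch date is estimable.
#' @export
compute_windows <- function(nests, years) {
  ph <- matrix(NA_integer_, length(years), 2,
               dimnames = list(years, c("start", "end")))
  pf <- ph
  for (i in seq_along(years)) {
    sub <- nests[nests$year == years[i] & !is.na(nests$first_egg_doy), ]
    if (!nrow(sub)) next
    h <- hatch_date(sub$first_egg_doy, pmax(sub$clutch, 1))
    ph[i, ] <- posthatch_window(h)
    pf[i, ] <- postfledge_window(h)
  }
  list(posthatch = ph, postfledge = pf)
}

#' Standardized annual environmental covariates
#'
#' Aggregates daily weather over phenology-anchored windows (post-hatching
#' rain and minimum temperature; post-fledging rain) and z-standardizes each
#' covariate across years. Years with no estimable window may borrow windows
#' from a donor (see `donor_windows`).
#'
#' @param weather Weather data frame.
#' @param windows Output of [compute_windows()].
#' @param years Study years (calendar years matching the weather dates).
#' @param donor_windows Optional [compute_windows()] result used to fill
#'   years whose own windows are missing.
#' @return Data frame `year, rain_ph, temp_ph, rain_pf` (standardized) with
#'   a logical attribute matrix `"missing"` and standardization metadata.
#' @export
build_covariates <- function(weather, windows, years, donor_windows = NULL) {
  fill <- function(w, dw) {
    if (is.null(dw)) return(w)
    miss <- is.na(w[, 1])
    w[miss, ] <- dw[miss, , drop = FALSE]
    w
  }
  ph <- fill(windows$posthatch, donor_windows$posthatch)
  pf <- fill(windows$postfledge, donor_windows$postfledge)
  raw <- data.frame(
    year = years,
    rain_ph = sapply(seq_along(years), function(i)
      aggregate_covariate(weather, years[i], ph[i, ], "rain_mm")),
    temp_ph = sapply(seq_along(years), function(i)
      aggregate_covariate(weather, years[i], ph[i, ], "tmin_c")),
    rain_pf = sapply(seq_along(years), function(i)
      aggregate_covariate(weather, years[i], pf[i, ], "rain_mm")))
  out <- raw
  meta <- list()
  for (v in c("rain_ph", "temp_ph", "rain_pf")) {
    z <- zstandardize(raw[[v]])
    out[[v]] <- as.numeric(z)
    meta[[v]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
  }
  attr(out, "missing") <- is.na(raw[c("rain_ph", "temp_ph", "rain_pf")])
  attr(out, "standardization") <- meta
  out
}
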