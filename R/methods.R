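#' @export
print.ipm_fit <- function(x, ...) {
  cfg <- x$config
  n_draws <- nrow(x$chains[[1]])
  top <- intersect(.top_level_params(), names(x$rhat))
  cat("Integrated population model fit\n")
  cat(sprintf("  years: %d-%d (%d)\n", min(x$years), max(x$years),
              length(x$years)))
  cat(sprintf("  components: %s\n", paste(x$components, collapse = ", ")))
  cat(sprintf("  chains: %d x %d retained draws (of %d iterations, burn-in %d, thin %d)\n",
              length(x$chains), n_draws, cfg$n_iter, cfg$n_burnin, cfg$thin))
  cat(sprintf("  max R-hat (top-level): %.3f\n",
              suppressWarnings(max(x$rhat[top], na.rm = TRUE))))
  if (length(x$flagged_chains)) {
    cat("  flagged chains:", paste(x$flagged_chains, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ipm_fit <- function(object, exclude_flagged = FALSE, ...) {
  s <- .summarize_draws(object, exclude_flagged)
  top <- s[s$parameter %in% .top_level_params(), ]
  top$rhat <- object$rhat[top$parameter]
  structure(list(top = top, full = s, fit = object),
            class = "summary.ipm_fit")
}

#' @export
print.summary.ipm_fit <- function(x, ...) {
  print.ipm_fit(x$fit)
  cat("\nTop-level parameters (median [95% CrI]):\n")
  tt <- x$top
  out <- data.frame(parameter = tt$parameter,
                    estimate = sprintf("%.3f [%.3f, %.3f]", tt$median,
                                       tt$lower95, tt$upper95),
                    rhat = round(tt$rhat, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ipm_fit <- function(object, ...) {
  s <- object$summary
  setNames(s$median, s$parameter)[.top_level_params()]
}

#' Posterior predictive comparison against the observed count streams
#' @param object An `ipm_fit`.
#' @param ... Passed to [posterior_predictive_table()].
#' @export
predict.ipm_fit <- function(object, ...) {
  posterior_predictive_table(object, ...)
}

#' Stochastic forward projection (simulate method)
#' @param object An `ipm_fit`.
#' @param nsim Replicate trajectories.
#' @param seed Seed.
#' @param horizon Years to project.
#' @param ... Passed to [forward_projection_check()].
#' @export
simulate.ipm_fit <- function(object, nsim = 1000, seed = 1, horizon = 10,
                             ...) {
  forward_projection_check(object, horizon = horizon, reps = nsim,
                           seed = seed, ...)
}

#' @export
plot.ipm_fit <- function(x, ...) {
  lat <- latent_state_draws(x)
  Ntot <- lat$N_Y + lat$N_A
  med <- apply(Ntot, 2, median)
  lo <- apply(Ntot, 2, quantile, 0.025)
  hi <- apply(Ntot, 2, quantile, 0.975)
  plot(x$years, med, type = "l", lwd = 2, ylim = range(0, hi),
       xlab = "Year", ylab = "Total females",
       main = "Estimated total population size", ...)
  graphics::polygon(c(x$years, rev(x$years)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$years, med, lwd = 2, col = "steelblue4")
  graphics::points(x$years, x$data$counts$first_clutches, pch = 16,
                   cex = 0.7)
  invisible(x)
}

#' @export
print.ltre_contributions <- function(x, ...) {
  cat(sprintf("Transient LTRE (%s design), reference: %s\n", x$design,
              x$reference))
  if (is.matrix(x$contributions)) {
    cat(sprintf("  %d year-steps; mean |total| = %.4f\n",
                ncol(x$contributions), mean(abs(x$total))))
  } else {
    df <- data.frame(parameter = names(x$contributions),
                     group = unname(x$groups),
                     contribution = round(unname(x$contributions), 6))
    print(df, row.names = FALSE)
    cat(sprintf("  total = %.6f\n", x$total))
  }
  invisible(x)
}

#' @export
print.posterior_ltre <- function(x, ...) {
  cat(sprintf("Posterior transient LTRE (%s design), %d draws\n",
              x$design, nrow(x$draws)))
  gs <- x$group_summary
  gs[-1] <- round(gs[-1], 5)
  print(gs, row.names = FALSE)
  invisible(x)
}

#' @export
print.ipm_data <- function(x, ...) {
  cat("IPM data bundle\n")
  cat(sprintf("  years %d-%d; %d nests; %d capture histories\n",
              min(x$years), max(x$years), nrow(x$nests),
              length(x$captures$individual)))
  cat(sprintf("  known-age reproduction records: %d\n", nrow(x$repro)))
  invisible(x)
}

#' @export
print.ipm_simulation <- function(x, ...) {
  cat("Simulated IPM dataset\n")
  cat(sprintf("  years %d-%d; %d nests; %d individuals in capture data\n",
              min(x$years), max(x$years), nrow(x$nests),
              length(unique(x$captures$individual))))
  invisible(x)
}

#' @export
print.ipm_projection <- function(x, ...) {
  cat(sprintf("Stochastic projection: %d replicates x %d years\n",
              x$reps, x$n_years))
  invisible(x)
}
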