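#' @export
print.alaam <- function(x, ...) {
  cat("Multilevel ALAAM fit (Robbins-Monro MCMC-MLE)\n")
  cat(sprintf("  %d households, %d regions, %d effects; seed %d\n",
              x$n_house, if (x$has_regions) x$n_region else 0L,
              length(x$coefficients), x$seed))
  cat(sprintf("  converged: %s (max |conv t| = %.3f%s)\n",
              x$converged, max(abs(x$conv_t)),
              if (x$restarts) sprintf(", %d restart(s)", x$restarts) else ""))
  print(round(cbind(theta = x$coefficients, se = x$std_err), 4))
  invisible(x)
}

#' Summarise a fitted multilevel ALAAM
#'
#' Reports, per effect: the estimated conditional log-odds `theta`, its
#' standard error, the odds multiplier `exp(theta)` (the factor by which
#' one additional unit of the configuration multiplies the odds of the
#' outcome, all else equal), the implied percentage change in the odds,
#' convergence t-ratios, and the count of adequately reproduced
#' goodness-of-fit statistics.
#'
#' @param object an [alaam()] fit.
#' @param ... unused.
#' @return object of class `"summary.alaam"`.
#' @export
summary.alaam <- function(object, ...) {
  est <- theta_odds(object$coefficients)
  tab <- cbind(est, se = object$std_err,
               lower = object$coefficients - 1.96 * object$std_err,
               upper = object$coefficients + 1.96 * object$std_err,
               conv_t = object$conv_t)
  structure(list(coefficients = tab, converged = object$converged,
                 gof = object$gof, control = object$control,
                 n_house = object$n_house, n_region = object$n_region,
                 n_missing = object$n_missing, call = object$call),
            class = "summary.alaam")
}

#' @export
print.summary.alaam <- function(x, ...) {
  cat("Multilevel ALAAM\n\nCall: ")
  print(x$call)
  cat("\nEffects (conditional log-odds):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\nConverged: %s (threshold %.2f on |conv_t|)\n",
              x$converged, x$control$conv_tol))
  bad <- x$gof[!x$gof$adequate & !is.na(x$gof$adequate), "statistic"]
  cat(sprintf("GOF: %d/%d statistics adequate (|t| < %.2f)%s\n",
              sum(x$gof$adequate, na.rm = TRUE), nrow(x$gof),
              x$control$gof_threshold,
              if (length(bad)) paste0("; inadequate: ",
                                      paste(bad, collapse = ", ")) else ""))
  invisible(x)
}

#' Odds-scale interpretation of ALAAM parameters
#'
#' Converts conditional log-odds parameters to odds multipliers and
#' percentage odds changes: a coefficient of -0.14, say, is an odds
#' multiplier of about 0.87, i.e. a 13% reduction in the odds per unit of
#' the configuration.
#'
#' @param theta named numeric vector of log-odds parameters.
#' @return data frame with `theta`, `odds_multiplier`, `percent_change`.
#' @export
theta_odds <- function(theta) {
  data.frame(theta = as.numeric(theta),
             odds_multiplier = exp(as.numeric(theta)),
             percent_change = 100 * (exp(as.numeric(theta)) - 1),
             row.names = names(theta))
}

#' @export
coef.alaam <- function(object, ...) object$coefficients

#' @export
vcov.alaam <- function(object, ...) object$vcov

#' @export
confint.alaam <- function(object, parm, level = 0.95, ...) {
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$std_err,
              object$coefficients + zq * object$std_err)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate outcome states from a fitted multilevel ALAAM
#'
#' @param object an [alaam()] fit.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param n_burn,thin sampler settings.
#' @param ... unused.
#' @return list with `y_draws`, `Y_draws` and the statistics of each draw.
#' @export
simulate.alaam <- function(object, nsim = 1, seed = 1L, n_burn = 500L,
                           thin = 5L, ...) {
  simulate_outcomes(object$net, object$effects, object$coefficients,
                    object$covariates, object$region_covariates,
                    object$quintile, n_burn = n_burn, n_draws = nsim,
                    thin = thin, seed = seed, return_states = TRUE)
}

#' Goodness-of-fit t-ratio plot for a fitted ALAAM
#'
#' Horizontal bars of the GOF t-ratios for every implemented statistic,
#' with the adequacy band at +-1.96 marked.
#'
#' @param x an [alaam()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.alaam <- function(x, ...) {
  g <- x$gof[!is.na(x$gof$t_ratio), ]
  bp <- barplot(g$t_ratio, names.arg = g$statistic, horiz = TRUE, las = 1,
                col = ifelse(g$in_model, "steelblue", "grey70"),
                xlab = "GOF t-ratio", ...)
  abline(v = c(-x$control$gof_threshold, x$control$gof_threshold), lty = 2)
  invisible(bp)
}
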