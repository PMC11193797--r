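#' Sampler and estimation settings for [alaam()]
#'
#' Units are full Gibbs sweeps (one sweep updates every free household and
#' region node once, in a freshly shuffled order).
#'
#' @param phase1_burn,phase1_n burn-in sweeps and number of draws used to
#'   scale the stochastic-approximation steps.
#' @param steps sweeps between successive draws (phases 1 and 2).
#' @param a0 initial Robbins-Monro gain; halved at each sub-phase.
#' @param subphases number of phase-2 sub-phases.
#' @param phase2_base,phase2_growth iterations in the first sub-phase and
#'   the growth factor of later ones.
#' @param phase3_burn,phase3_n,thin3 burn-in, sample size and thinning of
#'   the final convergence/GOF sample.
#' @param conv_tol convergence threshold on the |t-ratio| of every modelled
#'   statistic (0.1, the conventional value for stochastic-approximation
#'   fits of these models).
#' @param gof_threshold adequacy threshold on GOF t-ratios (1.96).
#' @param max_restarts extra phase-2 passes allowed when not converged.
#' @return list of class `"alaam_control"`.
#' @export
alaam_control <- function(phase1_burn = 50L, phase1_n = 100L, steps = 10L,
                          a0 = 0.1, subphases = 5L, phase2_base = 50L,
                          phase2_growth = 1.5, phase3_burn = 100L,
                          phase3_n = 1000L, thin3 = 5L,
                          conv_tol = 0.1, gof_threshold = 1.96,
                          max_restarts = 2L) {
  structure(as.list(environment()), class = "alaam_control")
}

#' Simulate outcome states from a multilevel ALAAM
#'
#' Draws joint household/region outcome vectors from the model distribution
#' by Gibbs sampling, starting from `y0`/`Y0` (default all zero) and
#' applying `n_burn` full sweeps before recording.  Used both to generate
#' synthetic study outcomes at known parameters and inside estimation.
#'
#' @inheritParams alaam_statistics
#' @param theta named numeric parameter vector, aligned with `effects`.
#' @param y0,Y0 initial states (defaults: all zero).
#' @param clamp_h optional household indices whose outcome is held fixed.
#' @param n_burn burn-in sweeps.
#' @param n_draws number of recorded draws.
#' @param thin sweeps between recorded draws.
#' @param seed integer seed.
#' @param return_states record the full outcome vectors (not just
#'   statistics)?
#' @return list with `stats` (draws x effects matrix), `y`, `Y` (final
#'   state) and, if requested, `y_draws` / `Y_draws` matrices.
#' @export
simulate_outcomes <- function(net, effects, theta, covariates = NULL,
                              region_covariates = NULL, quintile = NULL,
                              y0 = NULL, Y0 = NULL, clamp_h = integer(0),
                              n_burn = 500L, n_draws = 1L, thin = 1L,
                              seed = 1L, return_states = TRUE) {
  cm <- compile_model(net, effects, covariates, region_covariates, quintile)
  stopifnot(length(theta) == nrow(effects), all(is.finite(theta)))
  if (is.null(y0)) y0 <- integer(cm$N)
  if (is.null(Y0)) Y0 <- integer(cm$R)
  upd_h <- setdiff(seq_len(cm$N), clamp_h) - 1L
  upd_r <- seq_len(cm$R) - 1L
  if (!any(effects$level %in% c("region", "cross"))) upd_r <- integer(0)
  set.seed(seed)
  out <- alaam_gibbs_cpp(cm$cpp, as.numeric(theta), as.integer(y0),
                         as.integer(Y0), as.integer(upd_h),
                         as.integer(upd_r), as.integer(n_burn),
                         as.integer(n_draws), as.integer(thin), return_states)
  colnames(out$stats) <- cm$effects$name
  out
}

state_from_bits <- function(s, n) as.integer(intToBits(s)[seq_len(n)] == 1)

#' Exact distribution of a small multilevel ALAAM
#'
#' Enumerates all `2^(N+R)` outcome states (refusing beyond 20 free nodes)
#' and returns their exact probabilities; the underlying statistics come
#' from the plain-R [alaam_statistics()], so this is an independent oracle
#' for the Gibbs sampler.
#'
#' @inheritParams alaam_statistics
#' @param theta parameter vector aligned with `effects`.
#' @return data frame with `state` (bit-encoded outcome vector: household
#'   bits first, then region bits) and `prob`; attributes `logkappa` (log
#'   normalising constant) and `state_stats` (the states x effects
#'   statistic matrix, reusable for likelihood profiles over `theta`).
#' @export
alaam_exact_probs <- function(net, effects, theta, covariates = NULL,
                              region_covariates = NULL, quintile = NULL) {
  N <- net$n_house
  R <- if (any(effects$level %in% c("region", "cross"))) net$n_region else 0L
  n <- N + R
  if (n > 20L) stop("exact enumeration limited to 20 nodes (got ", n, ")")
  cm <- compile_model(net, effects, covariates, region_covariates, quintile)
  states <- 0:(2^n - 1)
  S <- vapply(states, function(s) {
    b <- state_from_bits(s, n)
    stats_from_compiled(cm, net, b[seq_len(N)],
                        if (R) b[N + seq_len(R)] else NULL)
  }, numeric(nrow(effects)))
  S <- if (is.matrix(S)) t(S) else matrix(S, ncol = 1L)
  w <- drop(S %*% theta)
  mx <- max(w)
  kappa <- sum(exp(w - mx))
  probs <- exp(w - mx) / kappa
  structure(data.frame(state = states, prob = probs),
            logkappa = mx + log(kappa), n_house = N, n_region = R,
            state_stats = S)
}

#' Exact log-likelihood of an outcome state
#'
#' @inheritParams alaam_exact_probs
#' @param y,Y observed outcome state.
#' @return log-probability, with attribute `logkappa`.
#' @export
alaam_exact_loglik <- function(theta, net, effects, y, Y = NULL,
                               covariates = NULL, region_covariates = NULL,
                               quintile = NULL) {
  tab <- alaam_exact_probs(net, effects, theta, covariates,
                           region_covariates, quintile)
  z <- alaam_statistics(net, y, Y, effects, covariates, region_covariates,
                        quintile)
  structure(sum(theta * z) - attr(tab, "logkappa"),
            logkappa = attr(tab, "logkappa"))
}

#' Fit a multilevel ALAAM by Robbins-Monro MCMC maximum likelihood
#'
#' Solves the exponential-family moment condition
#' `E_theta[z] = z_observed` by three-phase stochastic approximation:
#' phase 1 scales the step size from a short simulation at the starting
#' values; phase 2 runs gain-halving sub-phases of updates
#' `theta <- theta - a D^-1 (z_sim - z_obs)` along a persistent Gibbs
#' chain; phase 3 draws a large sample at the estimate to compute
#' convergence t-ratios, standard errors (inverse simulated covariance of
#' the statistics) and goodness-of-fit t-ratios for the full implemented
#' statistic set, including effects not in the model.
#'
#' Missing household outcomes (`NA` in `y`) are either held at zero and
#' never updated (`missing = "clamp"`) or treated as latent: their
#' contribution to the observed statistics is integrated out by conditional
#' Gibbs imputation and they are re-sampled during model simulation
#' (`missing = "latent"`, the default).  With no missing outcomes the two
#' modes coincide exactly.
#'
#' @param y binary household outcome vector (NA = missing).
#' @param net an affiliated `"mlnet"`.
#' @param effects an [alaam_effects()] specification; must contain
#'   `h_density` (and `r_density` when region-level effects are present).
#' @param Y binary region outcome vector, required for region/cross
#'   effects.
#' @param covariates data frame of household covariates (keyed by
#'   `household_id` or aligned with `net$households`).
#' @param region_covariates data frame of region covariates.
#' @param quintile baseline wealth quintile per household (for
#'   `poorest_contagion`).
#' @param control an [alaam_control()].
#' @param missing `"latent"` or `"clamp"`.
#' @param gof_effects effect set used for goodness of fit; defaults to the
#'   full implemented list compatible with the supplied data.
#' @param seed integer seed; the fit is bit-reproducible given it.
#' @return an object of class `"alaam"`; see [summary.alaam()].
#' @export
alaam <- function(y, net, effects, Y = NULL, covariates = NULL,
                  region_covariates = NULL, quintile = NULL,
                  control = alaam_control(), missing = c("latent", "clamp"),
                  gof_effects = NULL, seed = 1L) {
  missing <- match.arg(missing)
  has_regions <- any(effects$level %in% c("region", "cross"))
  if (!"h_density" %in% effects$name)
    stop("effects must include h_density")
  if (has_regions && !"r_density" %in% effects$name)
    stop("region-level effects require r_density")
  if (has_regions && is.null(Y)) stop("region effects require Y")
  if (is.null(Y)) Y <- integer(net$n_region)

  if (is.null(gof_effects)) {
    gof_effects <- default_effects(
      covariates = if (is.null(covariates))
        character() else setdiff(names(covariates), "household_id"),
      region_covariates = if (is.null(region_covariates))
        character() else setdiff(names(region_covariates), "region_id"),
      regions = has_regions, poorest = !is.null(quintile))
  }
  # record statistics for the union of model and GOF effects
  extra <- gof_effects[!gof_effects$name %in% effects$name, , drop = FALSE]
  all_eff <- rbind(effects[names(extra)], extra)
  class(all_eff) <- class(effects)
  fit_idx <- match(effects$name, all_eff$name)
  P <- nrow(all_eff)

  cm <- compile_model(net, all_eff, covariates, region_covariates, quintile)
  miss_h <- which(is.na(y))
  y_obs <- y; y_obs[miss_h] <- 0L
  upd_h_all <- seq_len(cm$N) - 1L
  upd_h_free <- setdiff(seq_len(cm$N), if (missing == "clamp") miss_h else
    integer(0)) - 1L
  upd_r <- if (has_regions) seq_len(cm$R) - 1L else integer(0)

  # observed statistics; latent missingness integrates them by conditional
  # simulation with the observed outcomes clamped
  if (length(miss_h) && missing == "latent") {
    set.seed(split_seed(seed, 101L))
    cond <- alaam_gibbs_cpp(cm$cpp, init_theta_full(all_eff, fit_idx, effects,
                                                    y_obs, Y),
                            as.integer(y_obs), as.integer(Y),
                            as.integer(miss_h - 1L), integer(0),
                            control$phase1_burn, control$phase1_n,
                            control$steps, FALSE)
    z_obs <- colMeans(cond$stats)
  } else {
    z_obs <- as.numeric(alaam_stats_cpp(cm$cpp, as.integer(y_obs),
                                        as.integer(Y)))
  }
  names(z_obs) <- all_eff$name

  theta <- numeric(P)
  theta[fit_idx] <- effects$theta
  dens_h <- match("h_density", all_eff$name)
  if (theta[dens_h] == 0)
    theta[dens_h] <- qlogis(min(max(mean(y_obs), 0.02), 0.98))
  if (has_regions) {
    dens_r <- match("r_density", all_eff$name)
    if (!is.na(dens_r) && theta[dens_r] == 0)
      theta[dens_r] <- qlogis(min(max(mean(Y), 0.02), 0.98))
  }

  run <- function(th, y0, Y0, n_burn, n_keep, thin) {
    alaam_gibbs_cpp(cm$cpp, th, as.integer(y0), as.integer(Y0),
                    as.integer(upd_h_free), as.integer(upd_r),
                    as.integer(n_burn), as.integer(n_keep),
                    as.integer(thin), FALSE)
  }

  set.seed(split_seed(seed, 102L))
  # phase 1: step scaling from a short pilot sample
  p1 <- run(theta, y_obs, Y, control$phase1_burn, control$phase1_n,
            control$steps)
  D <- pmax(apply(p1$stats[, fit_idx, drop = FALSE], 2, var), 1e-8)
  ycur <- p1$y; Ycur <- p1$Y

  phase2 <- function(theta) {
    for (k in seq_len(control$subphases)) {
      a <- control$a0 / 2^(k - 1)
      n_k <- ceiling(control$phase2_base * control$phase2_growth^(k - 1))
      acc <- matrix(0, n_k, length(fit_idx))
      for (it in seq_len(n_k)) {
        st <- run(theta, ycur, Ycur, control$steps, 1L, 1L)
        ycur <<- st$y; Ycur <<- st$Y
        z <- st$stats[1L, fit_idx]
        theta[fit_idx] <- theta[fit_idx] - a * (z - z_obs[fit_idx]) / D
        acc[it, ] <- theta[fit_idx]
      }
      theta[fit_idx] <- colMeans(acc[ceiling(n_k / 2):n_k, , drop = FALSE])
    }
    theta
  }

  converged <- FALSE
  restarts <- 0L
  repeat {
    theta <- phase2(theta)
    # phase 3: convergence check, SEs and GOF at the candidate estimate
    p3 <- run(theta, ycur, Ycur, control$phase3_burn, control$phase3_n,
              control$thin3)
    zbar <- colMeans(p3$stats)
    zsd <- apply(p3$stats, 2, sd)
    conv_t <- (zbar[fit_idx] - z_obs[fit_idx]) / pmax(zsd[fit_idx], 1e-12)
    converged <- max(abs(conv_t)) < control$conv_tol
    if (converged || restarts >= control$max_restarts) break
    restarts <- restarts + 1L
  }

  covz <- cov(p3$stats[, fit_idx, drop = FALSE])
  degenerate <- zsd[fit_idx] < 1e-10
  vc <- matrix(NA_real_, length(fit_idx), length(fit_idx))
  se <- rep(Inf, length(fit_idx))
  ok <- !degenerate
  if (any(ok)) {
    inv <- try(solve(covz[ok, ok, drop = FALSE]), silent = TRUE)
    if (!inherits(inv, "try-error")) {
      vc[ok, ok] <- inv
      se[ok] <- sqrt(diag(inv))
    }
  }
  gof_t <- (zbar - z_obs) / ifelse(zsd > 1e-10, zsd,
                                   ifelse(abs(zbar - z_obs) < 1e-10, 1, NA))
  gof <- data.frame(statistic = all_eff$name,
                    observed = as.numeric(z_obs),
                    sim_mean = as.numeric(zbar), sim_sd = as.numeric(zsd),
                    t_ratio = as.numeric(gof_t),
                    adequate = abs(gof_t) < control$gof_threshold,
                    in_model = all_eff$name %in% effects$name,
                    stringsAsFactors = FALSE)
  rownames(vc) <- colnames(vc) <- effects$name
  structure(list(
    coefficients = setNames(theta[fit_idx], effects$name),
    std_err = setNames(se, effects$name),
    conv_t = setNames(as.numeric(conv_t), effects$name),
    converged = converged, restarts = restarts,
    vcov = vc, gof = gof,
    z_obs = z_obs, effects = effects, gof_effects = all_eff,
    control = control, seed = seed, missing = missing,
    n_house = cm$N, n_region = cm$R, n_missing = length(miss_h),
    net = net, covariates = covariates,
    region_covariates = region_covariates, quintile = quintile,
    has_regions = has_regions, call = match.call()),
    class = "alaam")
}

init_theta_full <- function(all_eff, fit_idx, effects, y_obs, Y) {
  th <- numeric(nrow(all_eff))
  th[fit_idx] <- effects$theta
  dh <- match("h_density", all_eff$name)
  if (!is.na(dh) && th[dh] == 0)
    th[dh] <- qlogis(min(max(mean(y_obs), 0.02), 0.98))
  th
}

#' Goodness-of-fit by simulation at the fitted parameters
#'
#' Re-simulates the model at `coef(fit)` and reports, for every implemented
#' statistic, the t-ratio `(simulated mean - observed) / simulated sd` and
#' the adequacy flag `|t| < 1.96`.
#'
#' @param fit an [alaam()] fit.
#' @param n_samples number of simulated draws.
#' @param seed integer seed.
#' @param n_burn,thin sampler settings.
#' @return data frame like the `gof` element of the fit.
#' @export
gof <- function(fit, n_samples = 1000L, seed = 1L, n_burn = 500L, thin = 5L) {
  stopifnot(inherits(fit, "alaam"))
  all_eff <- fit$gof_effects
  theta <- numeric(nrow(all_eff))
  theta[match(fit$effects$name, all_eff$name)] <- fit$coefficients
  sim <- simulate_outcomes(fit$net, all_eff, theta, fit$covariates,
                           fit$region_covariates, fit$quintile,
                           n_burn = n_burn, n_draws = n_samples, thin = thin,
                           seed = seed, return_states = FALSE)
  zbar <- colMeans(sim$stats); zsd <- apply(sim$stats, 2, sd)
  t <- (zbar - fit$z_obs) / ifelse(zsd > 1e-10, zsd,
                                   ifelse(abs(zbar - fit$z_obs) < 1e-10, 1, NA))
  data.frame(statistic = all_eff$name, observed = as.numeric(fit$z_obs),
             sim_mean = as.numeric(zbar), sim_sd = as.numeric(zsd),
             t_ratio = as.numeric(t),
             adequate = abs(t) < fit$control$gof_threshold,
             in_model = all_eff$name %in% fit$effects$name,
             stringsAsFactors = FALSE)
}
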