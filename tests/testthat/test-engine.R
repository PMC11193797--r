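test_that("null and density-only models have the known marginals", {
  net <- toy_net8()
  eff <- alaam_effects("h_density")
  sim0 <- simulate_outcomes(net, eff, 0, n_burn = 100, n_draws = 2000,
                            thin = 1, seed = 1)
  expect_equal(mean(sim0$y_draws), 0.5, tolerance = 0.02)

  theta <- 0.8
  sim1 <- simulate_outcomes(net, eff, theta, n_burn = 100, n_draws = 2000,
                            thin = 1, seed = 2)
  expect_equal(mean(sim1$y_draws), plogis(theta), tolerance = 0.02)
})

test_that("exact log-likelihood has its closed forms and refuses large networks", {
  net <- tiny_net()
  eff <- alaam_effects("h_density")
  ll0 <- alaam_exact_loglik(0, net, eff, y = rep(0L, 5))
  expect_equal(as.numeric(ll0), -5 * log(2))
  # single free node at density theta: loglik(y=1) = theta - log(1+e^theta)
  one <- affiliate(build_ties(data.frame(individual_id = "i", household_id = "H",
                                         start_year = 2000, end_year = 2016)),
                   data.frame(household_id = "H", region_id = "r1"))
  th <- 0.7
  expect_equal(as.numeric(alaam_exact_loglik(th, one, eff, y = 1L)),
               th - log(1 + exp(th)))
  big <- random_net(n_ind = 200, n_house = 40, n_region = 3, seed = 5)
  expect_error(alaam_exact_probs(big, eff, 0), "20 nodes")
})

test_that("Gibbs draws match exact enumeration on a small multilevel network", {
  net <- tiny_net()  # 5 households + 2 regions = 7 nodes, 128 states
  eff <- alaam_effects(c("h_density", "same_region_contagion", "r_density",
                         "cross_level", "micro_macro"))
  theta <- c(-0.2, 0.5, -0.3, 0.3, 0.4)
  ex <- alaam_exact_probs(net, eff, theta)
  sim <- simulate_outcomes(net, eff, theta, n_burn = 200, n_draws = 1e5,
                           thin = 1, seed = 9)
  id <- drop(sim$y_draws %*% 2^(0:4) + sim$Y_draws %*% 2^(5:6))
  emp <- tabulate(id + 1, nbins = 128) / length(id)
  tv <- 0.5 * sum(abs(emp - ex$prob))
  expect_lt(tv, 0.02)
})

test_that("Robbins-Monro estimation matches the exact MLE on a small network", {
  net <- toy_net8()
  eff <- alaam_effects(c("h_density", "same_region_contagion"))
  y_obs <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  ml <- optim(c(0, 0), function(th)
    -alaam_exact_loglik(th, net, eff, y_obs), control = list(reltol = 1e-12))
  fit <- alaam(y_obs, net, eff,
               control = alaam_control(phase2_base = 100, phase3_n = 4000,
                                       steps = 20), seed = 5)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - ml$par)), 0.05)
  # moment condition at convergence
  expect_true(all(abs(fit$conv_t) < 0.1))
})

test_that("fits are reproducible and carry interpretable summaries", {
  net <- toy_net8()
  eff <- alaam_effects(c("h_density", "same_region_contagion"))
  y <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  ctl <- alaam_control(phase2_base = 20, phase3_n = 300)
  f1 <- alaam(y, net, eff, control = ctl, seed = 3)
  f2 <- alaam(y, net, eff, control = ctl, seed = 3)
  expect_identical(coef(f1), coef(f2))
  s <- summary(f1)
  expect_equal(s$coefficients$odds_multiplier,
               exp(s$coefficients$theta))
  ci <- confint(f1)
  expect_true(all(ci[, 1] < coef(f1) & coef(f1) < ci[, 2]))
})

test_that("clamped and latent missing-data modes coincide with an empty mask", {
  net <- toy_net8()
  eff <- alaam_effects(c("h_density", "same_region_contagion"))
  y <- c(1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L)
  ctl <- alaam_control(phase2_base = 20, phase3_n = 300)
  fl <- alaam(y, net, eff, control = ctl, missing = "latent", seed = 4)
  fc <- alaam(y, net, eff, control = ctl, missing = "clamp", seed = 4)
  expect_identical(coef(fl), coef(fc))
})

test_that("latent missing outcomes are imputed and the fit still runs", {
  net <- random_net(n_ind = 300, n_house = 60, n_region = 4, seed = 6)
  set.seed(7)
  y <- rbinom(60, 1, 0.5)
  y[sample(60, 8)] <- NA
  eff <- alaam_effects(c("h_density", "same_region_contagion"))
  ctl <- alaam_control(phase2_base = 20, phase3_n = 300)
  fit <- alaam(y, net, eff, control = ctl, missing = "latent", seed = 8)
  expect_equal(fit$n_missing, 8L)
  expect_true(all(is.finite(coef(fit))))
})

test_that("goodness of fit flags a strong omitted contagion effect", {
  set.seed(30)
  cfg <- generator_config(n_households = 600, n_regions = 6, seed = 30)
  pop <- simulate_population(cfg)
  gen_eff <- alaam_effects(c("h_density", "same_region_contagion"))
  sim <- simulate_outcomes(pop$net, gen_eff, c(-0.6, 1.2), n_burn = 400,
                           seed = 31)
  fit <- alaam(as.integer(sim$y), pop$net, alaam_effects("h_density"),
               control = alaam_control(phase2_base = 30, phase3_n = 500),
               seed = 32)
  g <- fit$gof
  expect_true(g$adequate[g$statistic == "h_density"])
  expect_gte(abs(g$t_ratio[g$statistic == "same_region_contagion"]), 1.96)
})

test_that("simulate() on a fit reproduces the modelled statistics on average", {
  net <- toy_net8()
  eff <- alaam_effects(c("h_density", "same_region_contagion"))
  y <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  fit <- alaam(y, net, eff,
               control = alaam_control(phase2_base = 50, phase3_n = 1000),
               seed = 11)
  sims <- simulate(fit, nsim = 500, seed = 12)
  zbar <- colMeans(sims$stats)
  expect_equal(unname(zbar["h_density"]),
               unname(fit$z_obs["h_density"]), tolerance = 0.25)
})
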