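full_spec <- function(with_cov = FALSE) {
  tms <- c("h_density", "h_connectivity", "h_closure",
           "same_region_connectivity", "cross_region_connectivity",
           "same_region_contagion", "cross_region_contagion",
           "poorest_contagion", "r_density", "r_connectivity",
           "r_cross_ties", "rr_contagion", "cross_level", "micro_macro")
  if (with_cov) tms <- c(tms, "external_ties", "external_ties_sq",
                         "cov:head_female", "rcov:inq")
  alaam_effects(tms)
}

test_that("effect lists put density terms first and reject unknown terms", {
  eff <- alaam_effects(c("same_region_contagion", "h_density", "r_density"))
  expect_equal(eff$name[1:2], c("h_density", "r_density"))
  expect_error(alaam_effects("transitive_wizardry"), "unknown effect")
  expect_error(alaam_effects(c("h_density", "h_density")), "unique")
})

test_that("statistics vanish on the all-zero state and match a hand count", {
  net <- tiny_net()
  eff <- full_spec()
  q <- c(1L, 1L, 3L, 4L, 5L)
  z0 <- alaam_statistics(net, rep(0L, 5), rep(0L, 2), eff, quintile = q)
  expect_true(all(z0 == 0))

  # h1-h2 same-region tie, both changed, their region changed:
  # one same-region concordant pair, two changed households in the region,
  # and the pair counts once in the micro-macro statistic
  y <- c(1L, 1L, 0L, 0L, 0L); Y <- c(1L, 0L)
  z <- alaam_statistics(net, y, Y, eff, quintile = q)
  expect_equal(unname(z["same_region_contagion"]), 1)
  expect_equal(unname(z["cross_level"]), 2)
  expect_equal(unname(z["micro_macro"]), 1)
  expect_equal(unname(z["poorest_contagion"]), 1)  # h1,h2 both poorest
  expect_equal(unname(z["h_density"]), 2)
  expect_equal(unname(z["r_density"]), 1)
})

test_that("statistics equal an independent loop-based recount on a random fixture", {
  net <- random_net(n_ind = 150, n_house = 30, n_region = 4, seed = 17)
  set.seed(18)
  y <- rbinom(net$n_house, 1, 0.5)
  Y <- rbinom(net$n_region, 1, 0.5)
  q <- sample(1:5, net$n_house, TRUE)
  cov <- data.frame(n_nonresidents = sample(0:6, net$n_house, TRUE),
                    head_female = rbinom(net$n_house, 1, 0.5))
  rc <- data.frame(inq = runif(net$n_region))
  eff <- full_spec(with_cov = TRUE)
  z <- alaam_statistics(net, y, Y, eff, covariates = cov,
                        region_covariates = rc, quintile = q)
  z_naive <- naive_statistics(net, y, Y, eff, covariates = cov,
                              quintile = q, region_covariates = rc)
  expect_equal(z, z_naive)
})

test_that("change statistics are local yet equal the global difference everywhere", {
  net <- random_net(n_ind = 150, n_house = 30, n_region = 4, seed = 19)
  set.seed(20)
  y <- rbinom(net$n_house, 1, 0.4)
  Y <- rbinom(net$n_region, 1, 0.4)
  q <- sample(1:5, net$n_house, TRUE)
  cov <- data.frame(n_nonresidents = sample(0:6, net$n_house, TRUE))
  eff <- alaam_effects(c("h_density", "h_connectivity", "h_closure",
                         "same_region_connectivity",
                         "cross_region_connectivity", "same_region_contagion",
                         "cross_region_contagion", "poorest_contagion",
                         "external_ties", "external_ties_sq", "r_density",
                         "r_connectivity", "r_cross_ties", "rr_contagion",
                         "cross_level", "micro_macro"))
  args <- list(net = net, effects = eff, covariates = cov, quintile = q)
  for (h in seq_len(net$n_house)) {
    y1 <- y; y1[h] <- 1L; y0 <- y; y0[h] <- 0L
    dz <- do.call(alaam_change_stats,
                  c(args, list(y = y, Y = Y, node = h, level = "household")))
    gd <- do.call(alaam_statistics, c(args, list(y = y1, Y = Y))) -
      do.call(alaam_statistics, c(args, list(y = y0, Y = Y)))
    expect_equal(dz, gd)
  }
  for (v in seq_len(net$n_region)) {
    Y1 <- Y; Y1[v] <- 1L; Y0 <- Y; Y0[v] <- 0L
    dz <- do.call(alaam_change_stats,
                  c(args, list(y = y, Y = Y, node = v, level = "region")))
    gd <- do.call(alaam_statistics, c(args, list(y = y, Y = Y1))) -
      do.call(alaam_statistics, c(args, list(y = y, Y = Y0)))
    expect_equal(dz, gd)
  }
})

test_that("change statistics of simple configurations are the textbook values", {
  net <- tiny_net()  # h5 is an isolate
  eff_d <- alaam_effects("h_density")
  dz <- alaam_change_stats(net, rep(0L, 5), NULL, eff_d, node = 5,
                           level = "household")
  expect_equal(unname(dz), 1)

  eff_c <- alaam_effects(c("h_density", "same_region_contagion"))
  # h2 is tied within-region to h1 and h3; set both partners to 1
  dz2 <- alaam_change_stats(net, c(1L, 0L, 1L, 0L, 0L), NULL, eff_c,
                            node = 2, level = "household")
  expect_equal(unname(dz2["same_region_contagion"]), 2)
})

test_that("a sweep of signed change statistics telescopes to the statistic difference", {
  net <- random_net(n_ind = 100, n_house = 25, n_region = 3, seed = 23)
  eff <- alaam_effects(c("h_density", "same_region_contagion",
                         "cross_region_contagion", "r_density",
                         "cross_level", "micro_macro"))
  set.seed(24)
  y <- rbinom(net$n_house, 1, 0.5); Y <- rbinom(net$n_region, 1, 0.5)
  z <- alaam_statistics(net, y, Y, eff)
  y2 <- y; Y2 <- Y
  acc <- 0 * z
  for (h in sample(net$n_house)) {
    new <- rbinom(1, 1, 0.5)
    if (new != y2[h]) {
      dz <- alaam_change_stats(net, y2, Y2, eff, node = h, level = "household")
      acc <- acc + (new - y2[h]) * dz
      y2[h] <- new
    }
  }
  for (v in sample(net$n_region)) {
    new <- rbinom(1, 1, 0.5)
    if (new != Y2[v]) {
      dz <- alaam_change_stats(net, y2, Y2, eff, node = v, level = "region")
      acc <- acc + (new - Y2[v]) * dz
      Y2[v] <- new
    }
  }
  expect_equal(alaam_statistics(net, y2, Y2, eff), z + acc)
})

test_that("missing covariates are reported by name", {
  net <- tiny_net()
  eff <- alaam_effects(c("h_density", "cov:wingspan"))
  expect_error(alaam_statistics(net, rep(0L, 5), NULL, eff,
                                covariates = data.frame(x = 1:5)),
               "wingspan")
})
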