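make_waves <- function(x1, x2) {
  ids <- sprintf("h%03d", seq_len(nrow(x1)))
  list(w1 = data.frame(household_id = ids, x1),
       w2 = data.frame(household_id = ids, x2))
}

test_that("a noise-free wealth gradient orders quintiles and affine rescaling leaves ranks alone", {
  set.seed(1)
  n <- 100
  dom <- seq_len(n)  # deterministic latent gradient, every item follows it
  x <- cbind(item_1 = dom, item_2 = 2 * dom + rnorm(n, sd = 0.01),
             item_3 = 0.5 * dom + rnorm(n, sd = 0.01))
  w <- make_waves(x, x)
  idx <- wealth_index(w$w1, w$w2)
  expect_equal(order(idx$score_w1), order(dom))
  expect_equal(idx$q_w1[which.max(dom)], 5L)
  expect_equal(idx$q_w1[which.min(dom)], 1L)

  x2 <- x; x2[, 1] <- 1000 + 7 * x2[, 1]
  w2 <- make_waves(x2, x2)
  idx2 <- wealth_index(w2$w1, w2$w2)
  expect_equal(rank(idx2$score_w1), rank(idx$score_w1))
})

test_that("constant items are dropped with a warning; too few items error", {
  set.seed(2)
  x <- cbind(item_1 = rnorm(10), item_2 = rep(1, 10), item_3 = rnorm(10))
  w <- make_waves(x, x)
  w$w2[c("item_1", "item_3")] <- w$w2[c("item_1", "item_3")] + 0.1
  # item_2 stays constant across the pooled waves
  expect_warning(idx <- wealth_index(w$w1, w$w2), "constant")
  expect_s3_class(idx, "wealth_index")
  xc <- cbind(item_1 = rnorm(10), item_2 = rep(1, 10))
  wc <- make_waves(xc, xc)
  expect_error(suppressWarnings(wealth_index(wc$w1, wc$w2)), "usable")
})

test_that("pooled quintiles are balanced within one household-wave", {
  set.seed(3)
  x1 <- matrix(rnorm(200 * 5), 200)
  x2 <- matrix(rnorm(200 * 5), 200)
  colnames(x1) <- colnames(x2) <- paste0("item_", 1:5)
  w <- make_waves(x1, x2)
  idx <- wealth_index(w$w1, w$w2)
  counts <- table(c(idx$q_w1, idx$q_w2))
  expect_equal(as.integer(names(counts)), 1:5)
  expect_true(all(abs(counts - 80) <= 1))
})

test_that("the PCA score recovers the generator's latent wealth", {
  cfg <- generator_config(n_households = 1500, n_regions = 6, seed = 8)
  pop <- simulate_population(cfg)
  idx <- wealth_index(pop$assets$wave1, pop$assets$wave2)
  rho <- cor(idx$score_w1, pop$assets$latent1, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("outcome modes encode quintile movements and partition households", {
  idx <- data.frame(household_id = c("a", "b", "c"),
                    q_w1 = c(2L, 2L, 4L), q_w2 = c(2L, 4L, 3L))
  expect_equal(household_outcome(idx, "any_change"), c(0L, 1L, 1L))
  expect_equal(household_outcome(idx, "stable"), c(1L, 0L, 0L))
  expect_equal(household_outcome(idx, "up"), c(0L, 1L, 0L))
  expect_equal(household_outcome(idx, "down"), c(0L, 0L, 1L))
  expect_error(household_outcome(idx, "sideways"))

  set.seed(4)
  big <- data.frame(household_id = sprintf("h%03d", 1:200),
                    q_w1 = sample(1:5, 200, TRUE), q_w2 = sample(1:5, 200, TRUE))
  tot <- household_outcome(big, "up") + household_outcome(big, "down") +
    household_outcome(big, "stable")
  expect_true(all(tot == 1L))
})

test_that("quintile-Gini matches the brute-force double sum and its invariances", {
  gini_bf <- function(x) {
    n <- length(x)
    if (n <= 1) return(0)
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
    s / (2 * n^2 * mean(x))
  }
  expect_equal(quintile_gini(c(3, 3, 3)), 0)
  expect_equal(quintile_gini(1:5), gini_bf(1:5))
  expect_equal(round(quintile_gini(1:5), 4), 0.2667)
  expect_equal(quintile_gini(1:5), 4 / 15)
  set.seed(5)
  for (rep in 1:20) {
    x <- sample(1:5, sample(2:12, 1), replace = TRUE)
    expect_equal(quintile_gini(x), gini_bf(x))
    expect_equal(quintile_gini(5 * x), quintile_gini(x))  # scale invariance
    expect_equal(quintile_gini(sample(x)), quintile_gini(x))  # order invariance
    expect_lte(quintile_gini(x), 0.8)
  }
  expect_equal(quintile_gini(7), 0)  # single-household region convention
})

test_that("regional outcome applies the 2% threshold and reports the percentile cut", {
  ineq <- data.frame(region_id = sprintf("r%02d", 1:5),
                     delta = c(0.025, 0.019, -0.03, 0.02, 0))
  Y <- regional_outcome(ineq)
  expect_equal(as.integer(Y), c(1L, 0L, 0L, 1L, 0L))
  expect_equal(attr(Y, "selected"), c("r01", "r04"))
  expect_equal(attr(Y, "percentile_cut"),
               mean(ineq$delta) + 0.675 * sd(ineq$delta))
  all0 <- regional_outcome(data.frame(region_id = "r1",
                                      delta = c(-0.1, 0, -0.02)))
  expect_true(all(all0 == 0L))
})

test_that("regional inequality counts match an independent per-region recount", {
  cfg <- generator_config(n_households = 600, n_regions = 23, seed = 12)
  pop <- simulate_population(cfg)
  idx <- wealth_index(pop$assets$wave1, pop$assets$wave2)
  ineq <- regional_inequality(idx, pop$affiliations)
  expect_equal(nrow(ineq), 23L)
  Y <- regional_outcome(ineq)
  expect_equal(sum(Y), sum(ineq$inq_w2 - ineq$inq_w1 >= 0.02))
  # spot-check one region against a direct recount
  r <- ineq$region_id[1]
  sel <- pop$affiliations$household_id[pop$affiliations$region_id == r]
  expect_equal(ineq$inq_w1[1],
               quintile_gini(idx$q_w1[idx$household_id %in% sel]))
})
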