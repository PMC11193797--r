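test_that("shared membership spells create ties with the stated shared-years convention", {
  # concurrent overlap 2005-2010 -> 6 calendar years
  eps <- data.frame(individual_id = c("i1", "i1"),
                    household_id = c("H1", "H2"),
                    start_year = c(2000, 2005), end_year = c(2016, 2010))
  net <- build_ties(eps)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$shared_years, 6)
  expect_equal(net$edges$n_shared_members, 1L)

  # sequential membership change still ties the households, with 0 shared years
  eps2 <- data.frame(individual_id = c("i1", "i1"),
                     household_id = c("H1", "H2"),
                     start_year = c(2000, 2010), end_year = c(2005, 2016))
  net2 <- build_ties(eps2)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$shared_years, 0)
})

test_that("invalid episodes are rejected with a warning and years are clipped", {
  eps <- data.frame(individual_id = c("i1", "i1", "i2"),
                    household_id = c("H1", "H2", "H1"),
                    start_year = c(2000, 2012, 1995),
                    end_year = c(2016, 2002, 2016))
  expect_warning(net <- build_ties(eps), "dropped")
  expect_equal(nrow(net$edges), 0L)  # only the bad record could have tied
})

test_that("tie construction matches an independent pairwise-overlap brute force", {
  eps <- random_episodes(n_ind = 90, n_house = 25, seed = 11)  # ~200 episodes
  net <- build_ties(eps)
  bf <- brute_force_ties(eps, net$households)
  got <- net$edges[order(net$edges$h1, net$edges$h2),
                   c("h1", "h2", "shared_years", "n_shared_members")]
  rownames(got) <- NULL
  expect_equal(got, bf)
})

test_that("tie construction is order-independent and monotone in individuals", {
  eps <- random_episodes(n_ind = 60, n_house = 20, seed = 7)
  net <- build_ties(eps, households = sprintf("h%02d", 1:20))
  set.seed(3)
  shuf <- eps[sample(nrow(eps)), ]
  net2 <- build_ties(shuf, households = sprintf("h%02d", 1:20))
  expect_equal(net$edges, net2$edges)

  # removing an individual can only remove ties
  drop <- unique(eps$individual_id)[5]
  net3 <- build_ties(eps[eps$individual_id != drop, ],
                     households = sprintf("h%02d", 1:20))
  key <- function(n) paste(n$edges$i, n$edges$j)
  expect_true(all(key(net3) %in% key(net)))
})

test_that("affiliation labels ties and derives the region meta-network", {
  eps <- data.frame(individual_id = c("a", "a", "b", "b"),
                    household_id = c("h1", "h2", "h2", "h3"),
                    start_year = 2000, end_year = 2016)
  one <- affiliate(build_ties(eps),
                   data.frame(household_id = paste0("h", 1:3),
                              region_id = "r1"))
  expect_equal(nrow(one$meta_edges), 0L)
  expect_true(all(one$edges$same_region))

  two <- affiliate(build_ties(eps),
                   data.frame(household_id = paste0("h", 1:3),
                              region_id = c("r1", "r1", "r2")))
  expect_equal(nrow(two$meta_edges), 1L)
  expect_equal(two$meta_edges$cross_tie_count, 1L)

  expect_error(affiliate(build_ties(eps),
                         data.frame(household_id = c("h1", "h2"),
                                    region_id = "r1")),
               "h3")
})

test_that("same/cross-region labels equal recomputation from the affiliation map", {
  net <- random_net(n_ind = 150, n_house = 40, n_region = 5, seed = 21)
  reg <- net$region
  expect_equal(net$edges$same_region,
               reg[net$edges$i] == reg[net$edges$j])
  # meta ties exactly the region pairs joined by >= 1 cross tie
  cross <- net$edges[!net$edges$same_region, ]
  pairs <- unique(t(apply(cbind(reg[cross$i], reg[cross$j]), 1, sort)))
  expect_equal(nrow(net$meta_edges), nrow(pairs))
})

test_that("network summary reproduces hand-computable topologies", {
  tri <- data.frame(individual_id = c("a", "a", "b", "b", "c", "c"),
                    household_id = c("h1", "h2", "h2", "h3", "h3", "h1"),
                    start_year = 2000, end_year = 2016)
  s <- network_summary(build_ties(tri))
  expect_equal(s$global_clustering, 1)
  expect_equal(s$mean_path_length, 1)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$largest_component_size, 3L)
})

test_that("summary agrees with an independent recomputation on a random fixture", {
  net <- random_net(n_ind = 200, n_house = 50, n_region = 4, seed = 31)
  s <- network_summary(net)
  expect_equal(s$mean_degree * s$n_nodes, 2 * s$n_edges)
  g <- igraph::graph_from_edgelist(cbind(net$edges$i, net$edges$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, net$n_house - igraph::vcount(g))
  expect_equal(s$global_clustering, igraph::transitivity(g, type = "global"))
  expect_equal(s$degree_sd, sd(igraph::degree(g)))
  comp <- igraph::components(g)
  expect_equal(s$largest_component_size, max(comp$csize))
  expect_equal(s$n_in_any_component, sum(igraph::degree(g) > 0))
})

test_that("topology benchmarks are size-matched and ER clustering is near k/n", {
  net <- random_net(n_ind = 400, n_house = 120, n_region = 5, seed = 41)
  tb <- topology_benchmarks(net, seed = 2)
  expect_equal(tb$model,
               c("observed", "erdos_renyi", "watts_strogatz",
                 "barabasi_albert"))
  expect_equal(tb$n_nodes, rep(net$n_house, 4))
  expect_equal(tb$n_edges[2], tb$n_edges[1])
  er_cl <- tb$global_clustering[2]
  expect_true(is.na(er_cl) || er_cl < 0.12)  # ~ mean_degree/n for ER
})
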