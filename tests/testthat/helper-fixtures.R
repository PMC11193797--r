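# Small in-code fixtures shared across the test files.

# 5 households in 2 regions: chain h1-h2-h3-h4 (h3-h4 crosses regions), h5 isolate
tiny_net <- function() {
  eps <- data.frame(
    individual_id = c("a", "a", "b", "b", "c", "c", "d"),
    household_id = c("h1", "h2", "h2", "h3", "h3", "h4", "h5"),
    start_year = c(2000, 2005, 2000, 2008, 2000, 2010, 2000),
    end_year = c(2016, 2010, 2016, 2012, 2016, 2016, 2016))
  affiliate(build_ties(eps),
            data.frame(household_id = paste0("h", 1:5),
                       region_id = c("r1", "r1", "r1", "r2", "r2")))
}

# 8 households, 2 regions, a triangle in each region plus a bridge
toy_net8 <- function() {
  eps <- data.frame(
    individual_id = rep(letters[1:8], each = 2),
    household_id = paste0("h", c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4, 3, 4, 7, 8)),
    start_year = 2000, end_year = 2016)
  affiliate(build_ties(eps, households = paste0("h", 1:8)),
            data.frame(household_id = paste0("h", 1:8),
                       region_id = rep(c("r1", "r2"), each = 4)))
}

# random membership episodes over n_house households
random_episodes <- function(n_ind = 120, n_house = 30, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_ind), function(i) {
    k <- sample(1:3, 1, prob = c(.6, .3, .1))
    h <- sample(n_house, k)
    s <- sample(2000:2014, k, replace = TRUE)
    data.frame(individual_id = sprintf("i%03d", i),
               household_id = sprintf("h%02d", h),
               start_year = s,
               end_year = pmin(s + sample(0:10, k, replace = TRUE), 2016))
  })
  do.call(rbind, rows)
}

random_net <- function(n_ind = 120, n_house = 30, n_region = 5, seed = 1) {
  eps <- random_episodes(n_ind, n_house, seed)
  set.seed(seed + 1)
  aff <- data.frame(household_id = sprintf("h%02d", 1:n_house),
                    region_id = sprintf("r%d", sample(n_region, n_house,
                                                      replace = TRUE)))
  affiliate(build_ties(eps, households = aff$household_id), aff)
}

# independent O(n^2) per-individual pairwise-overlap recount of ties
brute_force_ties <- function(episodes, households) {
  s <- pmax(episodes$start_year, 2000); e <- pmin(episodes$end_year, 2016)
  keep <- s <= e & episodes$end_year >= episodes$start_year
  episodes <- episodes[keep, ]; s <- s[keep]; e <- e[keep]
  years <- lapply(seq_len(nrow(episodes)), function(r) s[r]:e[r])
  res <- list()
  for (ind in unique(episodes$individual_id)) {
    rows <- which(episodes$individual_id == ind)
    hs <- unique(episodes$household_id[rows])
    if (length(hs) < 2) next
    yr <- lapply(hs, function(h)
      sort(unique(unlist(years[rows[episodes$household_id[rows] == h]]))))
    for (p in seq_along(hs)) for (q in seq_along(hs)) {
      if (p >= q) next
      a <- sort(c(hs[p], hs[q]))
      key <- paste(a, collapse = "|")
      ov <- min(length(intersect(yr[[p]], yr[[q]])), 16)
      res[[key]] <- c(res[[key]], ov)
    }
  }
  if (!length(res))
    return(data.frame(h1 = character(0), h2 = character(0),
                      shared_years = numeric(0), n_shared_members = integer(0)))
  keys <- sort(names(res))
  data.frame(h1 = sub("\\|.*", "", keys), h2 = sub(".*\\|", "", keys),
             shared_years = vapply(res[keys], mean, numeric(1)),
             n_shared_members = vapply(res[keys], length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# independent loop-based recount of every ALAAM statistic
naive_statistics <- function(net, y, Y, effects, covariates = NULL,
                             quintile = NULL, region_covariates = NULL) {
  N <- net$n_house; R <- net$n_region
  ed <- net$edges; reg <- net$region
  adj <- lapply(seq_len(N), function(h)
    c(ed$j[ed$i == h], ed$i[ed$j == h]))
  deg <- lengths(adj)
  tri <- vapply(seq_len(N), function(h) {
    nb <- adj[[h]]
    cnt <- 0L
    if (length(nb) >= 2) {
      pr <- combn(nb, 2)
      for (k in seq_len(ncol(pr)))
        if (pr[2, k] %in% adj[[pr[1, k]]]) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  poor <- if (is.null(quintile)) rep(0L, N) else as.integer(quintile == 1)
  z <- numeric(nrow(effects))
  for (p in seq_len(nrow(effects))) {
    nm <- effects$name[p]
    val <- 0
    if (nm == "h_density") {
      val <- sum(y)
    } else if (nm == "h_connectivity") {
      val <- sum(y * deg)
    } else if (nm == "h_closure") {
      val <- sum(y * tri)
    } else if (nm == "same_region_connectivity") {
      for (h in seq_len(N)) val <- val + y[h] * sum(reg[adj[[h]]] == reg[h])
    } else if (nm == "cross_region_connectivity") {
      for (h in seq_len(N)) val <- val + y[h] * sum(reg[adj[[h]]] != reg[h])
    } else if (nm == "same_region_contagion") {
      for (k in seq_len(nrow(ed))) {
        if (reg[ed$i[k]] == reg[ed$j[k]]) val <- val + y[ed$i[k]] * y[ed$j[k]]
      }
    } else if (nm == "cross_region_contagion") {
      for (k in seq_len(nrow(ed))) {
        if (reg[ed$i[k]] != reg[ed$j[k]]) val <- val + y[ed$i[k]] * y[ed$j[k]]
      }
    } else if (nm == "poorest_contagion") {
      for (k in seq_len(nrow(ed)))
        val <- val + y[ed$i[k]] * y[ed$j[k]] * poor[ed$i[k]] * poor[ed$j[k]]
    } else if (nm == "r_density") {
      val <- sum(Y)
    } else if (nm == "r_connectivity") {
      for (k in seq_len(nrow(ed))) {
        if (reg[ed$i[k]] == reg[ed$j[k]]) val <- val + Y[reg[ed$i[k]]]
      }
    } else if (nm == "r_cross_ties") {
      for (k in seq_len(nrow(ed))) {
        if (reg[ed$i[k]] != reg[ed$j[k]])
          val <- val + Y[reg[ed$i[k]]] + Y[reg[ed$j[k]]]
      }
    } else if (nm == "rr_contagion") {
      me <- net$meta_edges
      for (k in seq_len(nrow(me))) val <- val + Y[me$a[k]] * Y[me$b[k]]
    } else if (nm == "cross_level") {
      for (h in seq_len(N)) val <- val + y[h] * Y[reg[h]]
    } else if (nm == "micro_macro") {
      for (k in seq_len(nrow(ed))) {
        if (reg[ed$i[k]] == reg[ed$j[k]])
          val <- val + y[ed$i[k]] * y[ed$j[k]] * Y[reg[ed$i[k]]]
      }
    } else if (nm == "external_ties") {
      val <- sum(y * covariates$n_nonresidents)
    } else if (nm == "external_ties_sq") {
      val <- sum(y * covariates$n_nonresidents^2)
    } else if (startsWith(nm, "cov:")) {
      val <- sum(y * covariates[[sub("^cov:", "", nm)]])
    } else if (startsWith(nm, "rcov:")) {
      val <- sum(Y * region_covariates[[sub("^rcov:", "", nm)]])
    } else stop("naive recount missing effect: ", nm)
    z[p] <- val
  }
  setNames(z, effects$name)
}
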