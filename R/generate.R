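#' Configuration for the synthetic population generator
#'
#' Bundles every tunable of [simulate_population()].  Defaults are calibrated
#' so that, at full size (11,834 households across 23 regions), the implied
#' inter-household network has mean degree close to 1.72 and global
#' clustering close to 0.21, with a long-tailed degree distribution and a
#' strong within-region bias in tie formation.
#'
#' @param n_households number of households.
#' @param n_regions number of regions (administrative areas); default 23.
#' @param n_individuals total individuals; `NULL` derives ~7.83 per household.
#' @param mean_degree_target,clustering_target descriptive calibration targets
#'   recorded in the config (used by calibration checks, not by the sampler).
#' @param secondary_membership_rate probability that an individual holds a
#'   concurrent (or sequential) membership in a second household.
#' @param distance_decay rate of the exponential distance kernel governing
#'   which region a secondary membership lands in (`Inf` keeps all secondary
#'   memberships in the primary household's region).
#' @param triadic_closure_prob probability that a secondary membership closes
#'   a triangle (targets a two-step neighbour of the primary household).
#' @param sociality_sdlog log-sd of household attractiveness weights; larger
#'   values give heavier-tailed degree distributions.
#' @param move_fraction fraction of secondary memberships that are sequential
#'   membership changes (no concurrent years) rather than concurrent spells.
#' @param nonresident_rate probability a non-head member is a non-resident.
#' @param asset_items number of binary asset items per survey wave.
#' @param item_loadings,item_intercepts length-`asset_items` response
#'   parameters; defaults span moderate loadings and varied prevalences.
#' @param item_noise response noise scale; `0` gives deterministic thresholds.
#' @param wave_transition list with `stay_prob` (probability a household's
#'   latent wealth is carried over unchanged), `autocorr` (latent
#'   autocorrelation when it does move) and `contagion_strength` (influence
#'   of same-region network partners' baseline wealth on the wave-2 latent).
#' @param attrition fraction of households missing from the second wave.
#' @param seed integer seed; identical configs reproduce identical output.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(n_households = 11834L, n_regions = 23L,
                             n_individuals = NULL,
                             mean_degree_target = 1.72, clustering_target = 0.21,
                             secondary_membership_rate = 0.1105,
                             distance_decay = 8,
                             triadic_closure_prob = 0.59,
                             sociality_sdlog = 0.95,
                             move_fraction = 0.1,
                             nonresident_rate = 0.28,
                             asset_items = 20L,
                             item_loadings = NULL, item_intercepts = NULL,
                             item_noise = 1,
                             wave_transition = list(stay_prob = 0.2,
                                                    autocorr = 0.7,
                                                    contagion_strength = 0),
                             attrition = 0,
                             seed = 1L) {
  cfg <- list(n_households = as.integer(n_households),
              n_regions = as.integer(n_regions),
              n_individuals = if (is.null(n_individuals)) NULL else as.integer(n_individuals),
              mean_degree_target = mean_degree_target,
              clustering_target = clustering_target,
              secondary_membership_rate = secondary_membership_rate,
              distance_decay = distance_decay,
              triadic_closure_prob = triadic_closure_prob,
              sociality_sdlog = sociality_sdlog,
              move_fraction = move_fraction,
              nonresident_rate = nonresident_rate,
              asset_items = as.integer(asset_items),
              item_loadings = item_loadings,
              item_intercepts = item_intercepts,
              item_noise = item_noise,
              wave_transition = wave_transition,
              attrition = attrition,
              seed = as.integer(seed))
  if (is.null(cfg$item_loadings))
    cfg$item_loadings <- seq(0.8, 1.8, length.out = cfg$asset_items)
  if (is.null(cfg$item_intercepts))
    cfg$item_intercepts <- seq(-1.2, 1.2, length.out = cfg$asset_items)
  probs <- c(cfg$secondary_membership_rate, cfg$triadic_closure_prob,
             cfg$move_fraction, cfg$nonresident_rate,
             cfg$wave_transition$stay_prob, cfg$attrition)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all rate/probability parameters must lie in [0, 1]")
  if (cfg$n_households < 1L || cfg$n_regions < 1L)
    stop("counts must be positive")
  if (!all(is.finite(cfg$item_loadings)))
    stop("item_loadings must be finite")
  if (length(cfg$item_loadings) != cfg$asset_items)
    stop("item_loadings must have length asset_items")
  class(cfg) <- "generator_config"
  cfg
}

#' Assign households to the region of their nearest centroid
#'
#' @param coords n x 2 matrix of household coordinates.
#' @param centroids r x 2 matrix of region centroids.
#' @return integer vector of region indices (1-based).
#' @export
assign_regions <- function(coords, centroids) {
  coords <- as.matrix(coords); centroids <- as.matrix(centroids)
  d2 <- outer(coords[, 1], centroids[, 1], "-")^2 +
        outer(coords[, 2], centroids[, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Generate region centroids, household coordinates and affiliations
#'
#' Households cluster spatially around region centroids of unequal expected
#' size; each household is then affiliated to its nearest centroid.  The
#' first `n_regions` households are pinned to the centroids so no region is
#' ever empty.
#'
#' @param cfg a [generator_config()].
#' @return list with `centroids`, `coords`, `region` (integer index per
#'   household), `household_ids`, `region_ids` and an `affiliations`
#'   data frame.
#' @export
gen_geography <- function(cfg) {
  if (cfg$n_regions < 2L) stop("n_regions must be at least 2")
  if (cfg$n_regions > cfg$n_households)
    stop("n_regions exceeds n_households: configuration error")
  set.seed(split_seed(cfg$seed, 1L))
  R <- cfg$n_regions; N <- cfg$n_households
  centroids <- cbind(runif(R), runif(R))
  wts <- rgamma(R, shape = 5)
  home <- c(seq_len(R),
            sample.int(R, N - R, replace = TRUE, prob = wts / sum(wts)))
  spread <- 0.04
  coords <- centroids[home, , drop = FALSE] +
    cbind(c(rep(0, R), rnorm(N - R, 0, spread)),
          c(rep(0, R), rnorm(N - R, 0, spread)))
  region <- assign_regions(coords, centroids)
  household_ids <- sprintf("h%05d", seq_len(N))
  region_ids <- sprintf("r%02d", seq_len(R))
  list(centroids = centroids, coords = coords, region = region,
       household_ids = household_ids, region_ids = region_ids,
       affiliations = data.frame(household_id = household_ids,
                                 region_id = region_ids[region],
                                 stringsAsFactors = FALSE))
}

#' Generate membership episodes and household covariates
#'
#' Each household receives a set of primary members (one head plus a
#' Poisson-distributed number of others, ~28% of whom are non-resident
#' circular migrants).  A fraction of individuals acquires a second
#' membership: with probability `triadic_closure_prob` in a household two
#' steps away in the running tie graph (closing a triangle), otherwise in a
#' household drawn with probability proportional to a lognormal sociality
#' weight within a region drawn by exponential distance decay from the
#' primary household's region.  A `move_fraction` of these secondary events
#' are sequential membership changes with zero concurrent years.
#'
#' @param cfg a [generator_config()].
#' @param geography output of [gen_geography()].
#' @return list with `episodes` (data frame: individual_id, household_id,
#'   start_year, end_year, resident_flag) and `covariates` (one row per
#'   household: head_female, pension_eligible, mortality_any,
#'   n_nonresidents, any_nonresident, household_size).
#' @export
gen_membership <- function(cfg, geography) {
  set.seed(split_seed(cfg$seed, 2L))
  N <- cfg$n_households
  R <- cfg$n_regions
  mean_members <- if (is.null(cfg$n_individuals)) 7.83 else cfg$n_individuals / N
  n_members <- 1L + rpois(N, max(mean_members - 1, 0))
  n_ind <- sum(n_members)
  prim_house <- rep.int(seq_len(N), n_members)
  is_head <- sequence(n_members) == 1L
  resident <- is_head | (runif(n_ind) >= cfg$nonresident_rate)

  # secondary membership wiring
  cand <- which(runif(n_ind) < cfg$secondary_membership_rate)
  cand <- cand[sample.int(length(cand))]
  n_ev <- length(cand)

  # per-region sampling structures for the distance mechanism
  D <- as.matrix(stats::dist(geography$centroids))
  if (is.infinite(cfg$distance_decay)) {
    RW <- diag(R)
  } else {
    RW <- exp(-cfg$distance_decay * D)
  }
  RWc <- t(apply(RW, 1, function(w) cumsum(w / sum(w))))
  soc <- rlnorm(N, 0, cfg$sociality_sdlog)
  reg_h <- split(seq_len(N), geography$region)
  reg_cw <- lapply(reg_h, function(idx) {
    w <- soc[idx]; cumsum(w) / sum(w)
  })

  adj <- vector("list", N)
  sec_house <- integer(n_ev)
  is_move <- runif(n_ev) < cfg$move_fraction
  use_closure <- runif(n_ev) < cfg$triadic_closure_prob
  for (e in seq_len(n_ev)) {
    i <- cand[e]
    hp <- prim_house[i]
    hs <- 0L
    if (use_closure[e] && length(adj[[hp]])) {
      nb <- adj[[hp]]
      hn <- nb[sample.int(length(nb), 1L)]
      two <- setdiff(adj[[hn]], c(hp, nb))
      if (length(two)) hs <- two[sample.int(length(two), 1L)]
    }
    if (hs == 0L) {
      rp <- geography$region[hp]
      r <- findInterval(runif(1), RWc[rp, ]) + 1L
      if (r > R) r <- R
      idx <- reg_h[[r]]
      for (try in 1:4) {
        hs <- idx[findInterval(runif(1), reg_cw[[r]]) + 1L]
        if (is.na(hs)) hs <- idx[length(idx)]
        if (hs != hp) break
      }
      if (hs == hp) { sec_house[e] <- 0L; next }
    }
    if (!(hs %in% adj[[hp]])) {
      adj[[hp]] <- c(adj[[hp]], hs)
      adj[[hs]] <- c(adj[[hs]], hp)
    }
    sec_house[e] <- hs
  }
  ok <- sec_house > 0L
  cand <- cand[ok]; sec_house <- sec_house[ok]; is_move <- is_move[ok]
  n_ev <- length(cand)

  # primary episodes: full window, truncated for movers
  prim_start <- rep.int(.YEAR_MIN, n_ind)
  prim_end <- rep.int(.YEAR_MAX, n_ind)
  move_year <- integer(n_ev)
  sec_start <- integer(n_ev); sec_end <- integer(n_ev)
  if (n_ev) {
    move_year <- sample(seq(.YEAR_MIN + 1L, .YEAR_MAX), n_ev, replace = TRUE)
    dur <- rpois(n_ev, 5)
    sec_start <- ifelse(is_move, move_year,
                        pmin(.YEAR_MAX, sample(seq(.YEAR_MIN, .YEAR_MAX), n_ev,
                                               replace = TRUE)))
    sec_end <- ifelse(is_move, .YEAR_MAX, pmin(sec_start + dur, .YEAR_MAX))
    prim_end[cand[is_move]] <- move_year[is_move] - 1L
  }

  ind_ids <- sprintf("i%06d", seq_len(n_ind))
  episodes <- data.frame(
    individual_id = c(ind_ids, ind_ids[cand]),
    household_id = geography$household_ids[c(prim_house, sec_house)],
    start_year = c(prim_start, sec_start),
    end_year = c(prim_end, sec_end),
    resident_flag = c(resident, rep(FALSE, n_ev)),
    stringsAsFactors = FALSE)

  n_nonres <- tabulate(prim_house[!resident], nbins = N)
  n_res <- tabulate(prim_house[resident], nbins = N)
  covariates <- data.frame(
    household_id = geography$household_ids,
    head_female = rbinom(N, 1, 0.55),
    pension_eligible = rbinom(N, 1, 0.35),
    mortality_any = rbinom(N, 1, 0.15),
    n_nonresidents = pmin(n_nonres, 15L),
    any_nonresident = as.integer(n_nonres > 0L),
    household_size = pmin(n_res, 20L),
    stringsAsFactors = FALSE)
  list(episodes = episodes, covariates = covariates)
}

#' Generate two-wave binary asset items from a latent wealth score
#'
#' Wave-1 latent wealth is standard normal.  Item `j` is observed as a
#' logistic (or, at zero noise, threshold) response with loading
#' `item_loadings[j]` and intercept `item_intercepts[j]`.  With probability
#' `stay_prob` a household's wave-2 latent score and item responses are
#' carried over unchanged; otherwise the wave-2 latent is an autocorrelated
#' redraw optionally shifted by the mean centred baseline wealth quintile of
#' same-region network partners (`contagion_strength`).
#'
#' @param cfg a [generator_config()].
#' @param net an affiliated multilevel network (see [affiliate()]) whose
#'   households index the population; used for the contagion term.
#' @return list with `wave1`, `wave2` (household_id + item columns; wave-2
#'   rows missing under attrition), `latent1`, `latent2`.
#' @export
gen_assets <- function(cfg, net) {
  if (!all(is.finite(cfg$item_loadings))) stop("item_loadings must be finite")
  set.seed(split_seed(cfg$seed, 3L))
  N <- net$n_house
  k <- cfg$asset_items
  lam <- cfg$item_loadings; alp <- cfg$item_intercepts
  draw_items <- function(w) {
    eta <- outer(w, lam) + matrix(alp, N, k, byrow = TRUE)
    if (cfg$item_noise == 0) {
      m <- (eta > 0) + 0L
    } else {
      p <- plogis(eta / cfg$item_noise)
      m <- matrix(rbinom(N * k, 1, p), N, k)
    }
    colnames(m) <- sprintf("item_%02d", seq_len(k))
    m
  }
  w1 <- rnorm(N)
  x1 <- draw_items(w1)

  tr <- cfg$wave_transition
  q1 <- findInterval(w1, quantile(w1, c(.2, .4, .6, .8))) + 1L
  nbr <- numeric(N)
  if (!is.null(tr$contagion_strength) && tr$contagion_strength != 0 &&
      nrow(net$edges)) {
    same <- net$edges[net$edges$same_region, , drop = FALSE]
    if (nrow(same)) {
      contrib <- (q1 - 3) / 2
      s <- numeric(N); cnt <- numeric(N)
      for (col in c("i", "j")) {
        oth <- if (col == "i") same$j else same$i
        tgt <- same[[col]]
        s <- s + unname(tapply2(contrib[oth], tgt, N))
        cnt <- cnt + tabulate(tgt, nbins = N)
      }
      nbr <- ifelse(cnt > 0, s / pmax(cnt, 1), 0)
    }
  }
  stay <- runif(N) < tr$stay_prob
  rho <- if (is.null(tr$autocorr)) 0.7 else tr$autocorr
  w2 <- ifelse(stay, w1,
               rho * w1 + (if (is.null(tr$contagion_strength)) 0 else
                           tr$contagion_strength) * nbr +
                 sqrt(max(1 - rho^2, 0)) * rnorm(N))
  x2 <- draw_items(w2)
  x2[stay, ] <- x1[stay, ]

  keep2 <- rep(TRUE, N)
  if (cfg$attrition > 0)
    keep2[sample.int(N, round(cfg$attrition * N))] <- FALSE
  wave1 <- data.frame(household_id = net$households, x1,
                      stringsAsFactors = FALSE)
  wave2 <- data.frame(household_id = net$households[keep2],
                      x2[keep2, , drop = FALSE], stringsAsFactors = FALSE)
  list(wave1 = wave1, wave2 = wave2, latent1 = w1, latent2 = w2)
}

# grouped sum with fixed output length (base tapply drops empty groups)
tapply2 <- function(x, g, n) {
  out <- numeric(n)
  s <- tapply(x, g, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Simulate a complete synthetic study population
#'
#' Runs geography, membership, network construction and asset generation in
#' sequence and returns every artefact the analysis pipeline consumes.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return object of class `"synthetic_population"`: `episodes`,
#'   `affiliations`, `covariates` (including `mean_tie_years` from the built
#'   network), `assets` (wave1/wave2/latents), `net` (the affiliated
#'   [build_ties()] network), `geography`, `config`.
#' @export
simulate_population <- function(cfg = generator_config()) {
  geo <- gen_geography(cfg)
  mem <- gen_membership(cfg, geo)
  net <- affiliate(build_ties(mem$episodes, households = geo$household_ids),
                   geo$affiliations)
  assets <- gen_assets(cfg, net)
  cov <- mem$covariates
  cov$mean_tie_years <- mean_tie_years(net)
  structure(list(episodes = mem$episodes, affiliations = geo$affiliations,
                 covariates = cov, assets = assets, net = net,
                 geography = geo, config = cfg),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic population:", x$config$n_households, "households,",
      x$config$n_regions, "regions,",
      length(unique(x$episodes$individual_id)), "individuals\n")
  cat("  membership episodes:", nrow(x$episodes),
      "| inter-household ties:", nrow(x$net$edges), "\n")
  invisible(x)
}

#' Write a synthetic population to CSV/JSON files
#'
#' Emits `episodes.csv`, `affiliations.csv`, `assets_wave1.csv`,
#' `assets_wave2.csv` and `truth.json` (latent wealth and, when supplied,
#' the data-generating parameter vector).
#'
#' @param pop a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @param true_theta optional named numeric vector stored in `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, true_theta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(pop$episodes, file.path(dir, "episodes.csv"), row.names = FALSE)
  write.csv(pop$affiliations, file.path(dir, "affiliations.csv"),
            row.names = FALSE)
  write.csv(pop$assets$wave1, file.path(dir, "assets_wave1.csv"),
            row.names = FALSE)
  write.csv(pop$assets$wave2, file.path(dir, "assets_wave2.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(theta = as.list(true_theta),
                            latent_wealth_w1 = pop$assets$latent1,
                            latent_wealth_w2 = pop$assets$latent2,
                            seed = pop$config$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
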