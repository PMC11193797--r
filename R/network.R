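#' Build inter-household ties from membership episodes
#'
#' Two households are tied if at least one individual held a membership in
#' both at any time in the 2000-2016 window -- concurrently or sequentially
#' (a member who changed households still links them).  Each tie records the
#' number of shared members and `shared_years`, the mean over shared members
#' of the count of calendar years of simultaneous membership (0 for purely
#' sequential ties; capped at 16).
#'
#' @param episodes data frame with columns `individual_id`, `household_id`,
#'   `start_year`, `end_year` (and optionally `resident_flag`).  Years are
#'   clipped to 2000-2016; records with `end_year < start_year` are dropped
#'   with a warning.
#' @param households optional full household id vector (so households with
#'   members but no ties, or known isolates, appear as nodes); defaults to
#'   the ids present in `episodes`.
#' @return an object of class `"mlnet"` with `households`, `n_house` and an
#'   `edges` data frame (`i`, `j` node indices with `i < j`, `h1`, `h2` ids,
#'   `shared_years`, `n_shared_members`).  Region structure is added by
#'   [affiliate()].
#' @export
build_ties <- function(episodes, households = NULL) {
  need <- c("individual_id", "household_id", "start_year", "end_year")
  if (!all(need %in% names(episodes)))
    stop("episodes must have columns ", paste(need, collapse = ", "))
  bad <- episodes$end_year < episodes$start_year
  if (any(bad)) {
    warning(sum(bad), " episode(s) with end_year < start_year dropped")
    episodes <- episodes[!bad, , drop = FALSE]
  }
  s <- pmax(episodes$start_year, .YEAR_MIN)
  e <- pmin(episodes$end_year, .YEAR_MAX)
  keep <- s <= e
  episodes <- episodes[keep, , drop = FALSE]
  s <- s[keep]; e <- e[keep]

  if (is.null(households))
    households <- sort(unique(episodes$household_id))
  NH <- length(households)
  house <- match(episodes$household_id, households)
  if (anyNA(house)) stop("episodes reference unknown households")
  ind <- match(episodes$individual_id, unique(episodes$individual_id))

  # years as a 17-bit mask so concurrent overlap is a popcount of an AND
  mask <- as.integer(2^(e - .YEAR_MIN + 1) - 2^(s - .YEAR_MIN))

  # collapse duplicate (individual, household) episode rows by OR-ing masks
  key <- (ind - 1) * as.double(NH) + house
  if (anyDuplicated(key)) {
    g <- match(key, unique(key))
    mask <- as.integer(tapply(mask, g, function(m) Reduce(bitwOr, m)))
    first <- !duplicated(key)
    ind <- ind[first]; house <- house[first]
  }

  # only individuals belonging to >= 2 households can create ties
  cnt <- tabulate(ind)
  multi <- cnt[ind] >= 2L
  edges <- data.frame(i = integer(0), j = integer(0),
                      shared_years = numeric(0), n_shared_members = integer(0))
  if (any(multi)) {
    ind_m <- ind[multi]; house_m <- house[multi]; mask_m <- mask[multi]
    o <- order(ind_m)
    ind_m <- ind_m[o]; house_m <- house_m[o]; mask_m <- mask_m[o]
    grp <- split(seq_along(ind_m), ind_m)
    pr <- lapply(grp, function(ix) {
      cb <- combn(seq_along(ix), 2L)
      cbind(house_m[ix[cb[1, ]]], house_m[ix[cb[2, ]]],
            bitwAnd(mask_m[ix[cb[1, ]]], mask_m[ix[cb[2, ]]]))
    })
    pp <- do.call(rbind, pr)
    ii <- pmin(pp[, 1], pp[, 2]); jj <- pmax(pp[, 1], pp[, 2])
    same <- ii == jj   # duplicate household listings can't self-tie
    ii <- ii[!same]; jj <- jj[!same]; ov <- pp[!same, 3]
    if (length(ii)) {
      yrs <- pmin(popcount17(ov), .SHARED_YEARS_CAP)
      eid <- (ii - 1) * as.double(NH) + jj
      f <- factor(eid)
      u <- as.double(levels(f))
      edges <- data.frame(
        i = as.integer((u - 1) %/% NH + 1),
        j = as.integer((u - 1) %% NH + 1),
        shared_years = as.numeric(tapply(yrs, f, mean)),
        n_shared_members = as.integer(tabulate(f)))
      rownames(edges) <- NULL
    }
  }
  edges$h1 <- households[edges$i]
  edges$h2 <- households[edges$j]
  structure(list(households = households, n_house = NH, edges = edges,
                 region = NULL),
            class = "mlnet")
}

popcount17 <- function(x) {
  r <- integer(length(x))
  for (b in 0:16) r <- r + bitwAnd(bitwShiftR(x, b), 1L)
  r
}

#' Attach region affiliations and derive region meta-ties
#'
#' Labels every household tie as same-region or cross-region and derives the
#' region-level meta-network: two regions are meta-tied if at least one
#' household tie crosses between them.
#'
#' @param net an `"mlnet"` from [build_ties()].
#' @param affiliations data frame with `household_id`, `region_id`; every
#'   household in the network must appear exactly once.
#' @return the network with `region` (index per household), `region_ids`,
#'   `n_region`, a `same_region` flag on `edges`, and `meta_edges`
#'   (`a`, `b`, `cross_tie_count`).
#' @export
affiliate <- function(net, affiliations) {
  stopifnot(inherits(net, "mlnet"))
  if (anyDuplicated(affiliations$household_id))
    stop("duplicate household ids in affiliations")
  m <- match(net$households, affiliations$household_id)
  if (anyNA(m))
    stop("households missing from affiliations: ",
         paste(head(net$households[is.na(m)], 10L), collapse = ", "))
  region_id <- affiliations$region_id[m]
  region_ids <- sort(unique(affiliations$region_id))
  net$region <- match(region_id, region_ids)
  net$region_ids <- region_ids
  net$n_region <- length(region_ids)
  if (nrow(net$edges)) {
    ri <- net$region[net$edges$i]; rj <- net$region[net$edges$j]
    net$edges$same_region <- ri == rj
    cross <- !net$edges$same_region
    if (any(cross)) {
      a <- pmin(ri[cross], rj[cross]); b <- pmax(ri[cross], rj[cross])
      f <- factor((a - 1) * as.double(net$n_region) + b)
      u <- as.double(levels(f))
      net$meta_edges <- data.frame(
        a = as.integer((u - 1) %/% net$n_region + 1),
        b = as.integer((u - 1) %% net$n_region + 1),
        cross_tie_count = as.integer(tabulate(f)))
    } else {
      net$meta_edges <- data.frame(a = integer(0), b = integer(0),
                                   cross_tie_count = integer(0))
    }
  } else {
    net$edges$same_region <- logical(0)
    net$meta_edges <- data.frame(a = integer(0), b = integer(0),
                                 cross_tie_count = integer(0))
  }
  net
}

#' @export
print.mlnet <- function(x, ...) {
  cat("Multilevel household network:", x$n_house, "households,",
      nrow(x$edges), "ties")
  if (!is.null(x$region))
    cat(",", x$n_region, "regions,", nrow(x$meta_edges), "region meta-ties")
  cat("\n")
  invisible(x)
}

#' Household-level mean tie duration covariate
#'
#' Mean of `shared_years` over a household's incident ties; 0 for isolates.
#'
#' @param net an `"mlnet"`.
#' @return numeric vector aligned with `net$households`.
#' @export
mean_tie_years <- function(net) {
  s <- numeric(net$n_house); cnt <- numeric(net$n_house)
  if (nrow(net$edges)) {
    for (col in c("i", "j")) {
      idx <- net$edges[[col]]
      s <- s + tapply2(net$edges$shared_years, idx, net$n_house)
      cnt <- cnt + tabulate(idx, nbins = net$n_house)
    }
  }
  ifelse(cnt > 0, s / pmax(cnt, 1), 0)
}

#' Convert a multilevel network's household level to an igraph graph
#' @param net an `"mlnet"`.
#' @return an undirected igraph graph with isolates retained.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_house, directed = FALSE)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j))
  if (!is.null(net$region))
    g <- igraph::set_vertex_attr(g, "region", value = net$region)
  igraph::set_vertex_attr(g, "name", value = as.character(net$households))
}

graph_summary <- function(g, seed = 1L, exact_max = 3000L,
                          n_sample_sources = 200L) {
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  ns <- igraph::vcount(sub)
  if (ns <= 1L) {
    vals <- numeric(0)
  } else if (ns <= exact_max) {
    d <- igraph::distances(sub)
    vals <- d[upper.tri(d)]
  } else {
    # seeded source sampling: >= n_sample_sources * (ns - 1) >= 10^4 pairs
    set.seed(seed)
    src <- sample.int(ns, min(n_sample_sources, ns))
    d <- igraph::distances(sub, v = src)
    vals <- d[d > 0]
  }
  cl <- igraph::transitivity(g, type = "global")
  structure(list(
    n_nodes = n, n_edges = m,
    mean_degree = 2 * m / n,
    degree_sd = sd(deg),
    global_clustering = if (is.nan(cl)) NA_real_ else cl,
    mean_path_length = if (length(vals)) mean(vals) else NA_real_,
    path_length_sd = if (length(vals) > 1) sd(vals) else NA_real_,
    n_in_any_component = sum(deg > 0),
    largest_component_size = max(comp$csize)), class = "network_summary")
}

#' Summarise the topology of the household network
#'
#' Degree, global transitivity, component structure and mean shortest path
#' length on the largest component.  Path lengths are exact (all-pairs BFS)
#' up to `exact_max` nodes; above that, distances from a seeded sample of
#' source nodes are used (at least 10,000 sampled pairs).
#'
#' @param net an `"mlnet"` (or an igraph graph).
#' @param seed seed for path-length pair sampling on large components.
#' @param exact_max largest component size for exact all-pairs paths.
#' @param n_sample_sources number of BFS sources when sampling.
#' @return a `"network_summary"`: n_nodes, n_edges, mean_degree, degree_sd,
#'   global_clustering, mean_path_length, path_length_sd,
#'   n_in_any_component, largest_component_size.
#' @export
network_summary <- function(net, seed = 1L, exact_max = 3000L,
                            n_sample_sources = 200L) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  if (igraph::vcount(g) == 0L) stop("empty node set")
  graph_summary(g, seed = seed, exact_max = exact_max,
                n_sample_sources = n_sample_sources)
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  mean degree %.3f (sd %.3f), clustering %.3f\n",
              x$mean_degree, x$degree_sd, x$global_clustering))
  cat(sprintf("  mean path length %.2f (sd %.2f) on largest component (%d)\n",
              x$mean_path_length, x$path_length_sd, x$largest_component_size))
  invisible(x)
}

#' Compare the observed network to matched reference topologies
#'
#' Summaries of degree/size-matched Erdos-Renyi, Watts-Strogatz and
#' Barabasi-Albert graphs next to the observed network, for descriptive
#' placement of the empirical topology.
#'
#' @param net an `"mlnet"`.
#' @param seed seed for the random reference graphs.
#' @param ws_p Watts-Strogatz rewiring probability.
#' @return data frame with one row per model and the summary fields.
#' @export
topology_benchmarks <- function(net, seed = 1L, ws_p = 0.1) {
  g <- as_igraph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  k <- max(1L, round(m / n))
  set.seed(split_seed(seed, 11L))
  gs <- list(
    observed = g,
    erdos_renyi = igraph::sample_gnm(n, m),
    watts_strogatz = igraph::sample_smallworld(1, n, k, ws_p),
    barabasi_albert = igraph::sample_pa(n, m = k, directed = FALSE))
  rows <- lapply(names(gs), function(nm) {
    s <- graph_summary(gs[[nm]], seed = split_seed(seed, 12L))
    data.frame(model = nm, as.data.frame(unclass(s)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
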