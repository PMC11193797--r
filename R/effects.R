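#' Construct an ALAAM effect specification
#'
#' An ordered list of model configurations.  Built-in structural terms:
#'
#' * `h_density` -- household outcome count (intercept; always first).
#' * `h_connectivity` -- outcome x degree.
#' * `h_closure` -- outcome x number of triangles through the household.
#' * `same_region_connectivity`, `cross_region_connectivity` -- outcome x
#'   within-/cross-region degree (co-location and cross-location ties).
#' * `external_ties`, `external_ties_sq` -- outcome x number of non-resident
#'   members and its square (circular-migration exposure, inverted-U form).
#' * `same_region_contagion`, `cross_region_contagion` -- concordant tied
#'   pairs within/across regions (each unordered tie counted once).
#' * `poorest_contagion` -- concordant tied pairs with both households in
#'   the poorest baseline quintile.
#' * `r_density` -- region outcome count (region intercept).
#' * `r_connectivity`, `r_cross_ties` -- region outcome x number of
#'   household ties inside the region / crossing its boundary.
#' * `rr_contagion` -- concordant meta-tied region pairs.
#' * `cross_level` -- region outcome x count of outcome-positive households
#'   in the region.
#' * `micro_macro` -- region outcome x count of within-region concordant
#'   tied household pairs.
#'
#' Covariate terms are written `"cov:<name>"` (household) or
#' `"rcov:<name>"` (region), referring to columns of the covariate tables
#' handed to [alaam()] / [alaam_statistics()].
#'
#' @param terms character vector of term names as above.
#' @param theta optional numeric start values (recycled; default 0).
#' @return data frame of class `"alaam_effects"` with columns `name`,
#'   `level`, `code`, `covariate`, `theta`.
#' @export
alaam_effects <- function(terms, theta = 0) {
  builtin <- list(
    h_density = list(level = "household", code = 1L, covariate = ".one"),
    h_connectivity = list(level = "household", code = 1L, covariate = ".degree"),
    h_closure = list(level = "household", code = 1L, covariate = ".triangles"),
    same_region_connectivity = list(level = "household", code = 1L,
                                    covariate = ".degree_same"),
    cross_region_connectivity = list(level = "household", code = 1L,
                                     covariate = ".degree_cross"),
    external_ties = list(level = "household", code = 1L,
                         covariate = "n_nonresidents"),
    external_ties_sq = list(level = "household", code = 1L,
                            covariate = ".n_nonresidents_sq"),
    same_region_contagion = list(level = "household", code = 2L, covariate = NA),
    cross_region_contagion = list(level = "household", code = 3L, covariate = NA),
    poorest_contagion = list(level = "household", code = 4L, covariate = NA),
    r_density = list(level = "region", code = 5L, covariate = ".one"),
    r_connectivity = list(level = "region", code = 5L, covariate = ".within_ties"),
    r_cross_ties = list(level = "region", code = 5L, covariate = ".cross_ties"),
    rr_contagion = list(level = "region", code = 6L, covariate = NA),
    cross_level = list(level = "cross", code = 7L, covariate = NA),
    micro_macro = list(level = "cross", code = 8L, covariate = NA))
  rows <- lapply(terms, function(tm) {
    if (tm %in% names(builtin)) {
      b <- builtin[[tm]]
      data.frame(name = tm, level = b$level, code = b$code,
                 covariate = b$covariate, stringsAsFactors = FALSE)
    } else if (startsWith(tm, "cov:")) {
      data.frame(name = tm, level = "household", code = 1L,
                 covariate = sub("^cov:", "", tm), stringsAsFactors = FALSE)
    } else if (startsWith(tm, "rcov:")) {
      data.frame(name = tm, level = "region", code = 5L,
                 covariate = sub("^rcov:", "", tm), stringsAsFactors = FALSE)
    } else stop("unknown effect term: ", tm)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name)) stop("effect names must be unique")
  out$theta <- rep_len(theta, nrow(out))
  # density terms lead, in fixed order
  lead <- c(match("h_density", out$name), match("r_density", out$name))
  lead <- lead[!is.na(lead)]
  if (length(lead))
    out <- out[c(lead, setdiff(seq_len(nrow(out)), lead)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alaam_effects", "data.frame")
  out
}

#' Full effect list implemented by the package
#'
#' The complete menu of structural configurations plus covariate terms for
#' the supplied covariate names; used as the goodness-of-fit statistic set.
#'
#' @param covariates character vector of household covariate column names.
#' @param region_covariates character vector of region covariate columns.
#' @param regions include region-level and cross-level terms?
#' @param poorest include the poorest-dyad contagion term?
#' @return an [alaam_effects()] specification.
#' @export
default_effects <- function(covariates = character(),
                            region_covariates = character(),
                            regions = TRUE, poorest = FALSE) {
  tms <- c("h_density", "h_connectivity", "h_closure",
           "same_region_connectivity", "cross_region_connectivity",
           "same_region_contagion", "cross_region_contagion")
  if (poorest) tms <- c(tms, "poorest_contagion")
  if ("n_nonresidents" %in% covariates)
    tms <- c(tms, "external_ties", "external_ties_sq")
  tms <- c(tms, paste0("cov:", setdiff(covariates, "n_nonresidents"),
                       recycle0 = TRUE))
  if (regions)
    tms <- c(tms, "r_density", "r_connectivity", "r_cross_ties",
             "rr_contagion", "cross_level", "micro_macro",
             paste0("rcov:", region_covariates, recycle0 = TRUE))
  alaam_effects(tms)
}

# --- model compilation -----------------------------------------------------

csr <- function(i, j, n, flag = NULL) {
  o <- order(i)
  ptr <- c(0L, cumsum(tabulate(i, nbins = n)))
  out <- list(idx = as.integer(j[o] - 1L), ptr = as.integer(ptr))
  if (!is.null(flag)) out$flag <- flag[o]
  out
}

align_covariates <- function(tab, ids, what) {
  if (is.null(tab)) return(NULL)
  tab <- as.data.frame(tab)
  key <- intersect(c("household_id", "region_id"), names(tab))
  if (length(key)) {
    m <- match(ids, tab[[key[1]]])
    if (anyNA(m)) stop("missing ", what, " rows for some nodes")
    tab <- tab[m, setdiff(names(tab), key), drop = FALSE]
  } else if (nrow(tab) != length(ids)) {
    stop(what, " must have one row per node")
  }
  tab
}

# Turn a network + effect spec + covariates into the flat structure the
# compiled sampler consumes.  Derived structural covariates (degree,
# triangle counts, within/cross-region tie counts) are computed here.
compile_model <- function(net, effects, covariates = NULL,
                          region_covariates = NULL, quintile = NULL) {
  stopifnot(inherits(net, "mlnet"))
  if (is.null(net$region)) stop("network has no region affiliation; run affiliate()")
  N <- net$n_house; R <- net$n_region
  ed <- net$edges
  covariates <- align_covariates(covariates, net$households, "covariates")
  region_covariates <- align_covariates(region_covariates, net$region_ids,
                                        "region_covariates")

  deg <- tabulate(c(ed$i, ed$j), nbins = N)
  same <- if (nrow(ed)) ed$same_region else logical(0)
  deg_same <- tabulate(c(ed$i[same], ed$j[same]), nbins = N)
  deg_cross <- deg - deg_same
  tri <- if (nrow(ed)) igraph::count_triangles(as_igraph(net)) else rep(0, N)
  W <- tabulate(net$region[ed$i[same]], nbins = R)
  Cv <- tabulate(c(net$region[ed$i[!same]], net$region[ed$j[!same]]), nbins = R)

  hcol <- function(nm) {
    switch(nm,
           ".one" = rep(1, N), ".degree" = deg, ".triangles" = as.numeric(tri),
           ".degree_same" = deg_same, ".degree_cross" = deg_cross,
           ".n_nonresidents_sq" = {
             if (is.null(covariates) || !"n_nonresidents" %in% names(covariates))
               stop("effect needs covariate: n_nonresidents")
             covariates$n_nonresidents^2
           },
           {
             if (is.null(covariates) || !nm %in% names(covariates))
               stop("effect needs covariate: ", nm)
             as.numeric(covariates[[nm]])
           })
  }
  rcol <- function(nm) {
    switch(nm,
           ".one" = rep(1, R), ".within_ties" = as.numeric(W),
           ".cross_ties" = as.numeric(Cv),
           {
             if (is.null(region_covariates) || !nm %in% names(region_covariates))
               stop("effect needs region covariate: ", nm)
             as.numeric(region_covariates[[nm]])
           })
  }

  P <- nrow(effects)
  code <- effects$code
  col <- integer(P)
  hstat <- matrix(0, N, 0); rstat <- matrix(0, R, 0)
  for (p in seq_len(P)) {
    if (code[p] == 1L) {
      hstat <- cbind(hstat, hcol(effects$covariate[p])); col[p] <- ncol(hstat) - 1L
    } else if (code[p] == 5L) {
      rstat <- cbind(rstat, rcol(effects$covariate[p])); col[p] <- ncol(rstat) - 1L
    } else col[p] <- 0L
  }
  if (ncol(hstat) == 0) hstat <- matrix(0, N, 1)
  if (ncol(rstat) == 0) rstat <- matrix(0, R, 1)

  adj <- csr(c(ed$i, ed$j), c(ed$j, ed$i), N, rep(same, 2))
  radj <- csr(c(net$meta_edges$a, net$meta_edges$b),
              c(net$meta_edges$b, net$meta_edges$a), R)
  rh <- csr(net$region, seq_len(N), R)
  poorest <- if (is.null(quintile)) integer(N) else as.integer(quintile == 1L)
  if (any(code == 4L) && is.null(quintile))
    stop("poorest_contagion needs baseline quintiles")
  list(cpp = list(nb_idx = adj$idx, nb_ptr = adj$ptr, nb_same = adj$flag,
                  region = as.integer(net$region - 1L),
                  rnb_idx = radj$idx, rnb_ptr = radj$ptr,
                  rh_idx = rh$idx, rh_ptr = rh$ptr,
                  hstat = hstat, rstat = rstat,
                  code = as.integer(code), col = col,
                  poorest = poorest),
       effects = effects, N = N, R = R)
}

#' Compute ALAAM sufficient statistics
#'
#' Evaluates every configuration count `z_I(y, Y)` of an effect
#' specification on an observed outcome state.  This is a plain R
#' implementation, independent of the compiled sampler; the two are
#' cross-checked in the package tests.
#'
#' @param net an affiliated `"mlnet"`.
#' @param y binary household outcome vector (no NAs).
#' @param Y binary region outcome vector (`NULL` if regions are not
#'   modelled; region/cross effects then require it).
#' @param effects an [alaam_effects()] specification.
#' @param covariates,region_covariates covariate tables (see [alaam()]).
#' @param quintile baseline wealth quintile per household (1 = poorest),
#'   needed by `poorest_contagion`.
#' @return named numeric vector of statistics.
#' @export
alaam_statistics <- function(net, y, Y = NULL, effects,
                             covariates = NULL, region_covariates = NULL,
                             quintile = NULL) {
  if (anyNA(y) || (!is.null(Y) && anyNA(Y)))
    stop("statistics need complete outcomes; mask handling happens in alaam()")
  cm <- compile_model(net, effects, covariates, region_covariates, quintile)
  stats_from_compiled(cm, net, y, Y)
}

# plain-R statistic evaluation on a pre-compiled model (independent of the
# C++ sampler kernel; the compiled structure only carries static columns)
stats_from_compiled <- function(cm, net, y, Y = NULL) {
  if (is.null(Y)) Y <- integer(net$n_region)
  ed <- net$edges
  reg <- net$region
  effects <- cm$effects
  z <- numeric(nrow(effects))
  poorest <- cm$cpp$poorest
  conc <- if (nrow(ed)) y[ed$i] * y[ed$j] else numeric(0)
  for (p in seq_len(nrow(effects))) {
    z[p] <- switch(as.character(effects$code[p]),
      "1" = sum(y * cm$cpp$hstat[, cm$cpp$col[p] + 1L]),
      "2" = sum(conc[ed$same_region]),
      "3" = sum(conc[!ed$same_region]),
      "4" = sum(conc * poorest[ed$i] * poorest[ed$j]),
      "5" = sum(Y * cm$cpp$rstat[, cm$cpp$col[p] + 1L]),
      "6" = if (nrow(net$meta_edges))
        sum(Y[net$meta_edges$a] * Y[net$meta_edges$b]) else 0,
      "7" = sum(Y[reg] * y),
      "8" = if (nrow(ed)) sum(conc[ed$same_region] *
                              Y[reg[ed$i[ed$same_region]]]) else 0)
  }
  setNames(z, effects$name)
}

#' Change statistics for one node
#'
#' The vector `dz` by which every model statistic moves when `node`'s
#' outcome flips from 0 to 1, everything else held fixed.  Computed locally
#' from the node's incident ties and affiliation (the building block of the
#' Gibbs full conditional); exactly equals the global statistic difference.
#'
#' @inheritParams alaam_statistics
#' @param node node index (household index, or region index when
#'   `level = "region"`).
#' @param level `"household"` or `"region"`.
#' @return named numeric vector `dz`.
#' @export
alaam_change_stats <- function(net, y, Y = NULL, effects, node,
                               level = c("household", "region"),
                               covariates = NULL, region_covariates = NULL,
                               quintile = NULL) {
  level <- match.arg(level)
  if (is.null(Y)) Y <- integer(net$n_region)
  cm <- compile_model(net, effects, covariates, region_covariates, quintile)
  dz <- alaam_changestat_cpp(cm$cpp, as.integer(y), as.integer(Y),
                             as.integer(node - 1L), level == "household")
  setNames(as.numeric(dz), effects$name)
}
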