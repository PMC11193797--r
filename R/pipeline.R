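#' Configuration for the end-to-end study pipeline
#'
#' @param out_dir directory for stage artefacts.
#' @param generator a [generator_config()] for the synthetic population.
#' @param outcome_mode household outcome definition
#'   (see [household_outcome()]).
#' @param inequality_threshold regional outcome cut (see
#'   [regional_outcome()]).
#' @param effects ALAAM effect terms (character vector understood by
#'   [alaam_effects()]); `NULL` uses the full default specification.
#' @param control an [alaam_control()].
#' @param seed root seed for estimation stages (the generator carries its
#'   own seed).
#' @return list of class `"study_config"`.
#' @export
study_config <- function(out_dir = tempfile("mlalaam_study_"),
                         generator = generator_config(),
                         outcome_mode = "any_change",
                         inequality_threshold = 0.02,
                         effects = NULL,
                         control = alaam_control(),
                         seed = 1L) {
  structure(list(out_dir = out_dir, generator = generator,
                 outcome_mode = outcome_mode,
                 inequality_threshold = inequality_threshold,
                 effects = effects, control = control,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full synthetic study pipeline
#'
#' Executes simulate -> build-network -> wealth -> inequality -> baseline ->
#' fit-alaam -> gof -> report, writing each stage's artefacts
#' (`episodes.csv`, `affiliations.csv`, `edges.csv`, `summary.json`,
#' `wealth.csv`, `inequality.csv`, `baseline_fit.json`, `ame.csv`,
#' `nonresident_profile.csv`, `fit.json`, `gof.csv`, `report.md`) under
#' `config$out_dir` and logging households in/out of every filter.
#' Re-running with an identical config reproduces identical artefacts.
#'
#' @param config a [study_config()].
#' @param stages subset of stage names to run (default: all, in order).
#' @return list with every in-memory stage product and the stage log.
#' @export
run_study <- function(config = study_config(),
                      stages = c("simulate", "network", "wealth",
                                 "inequality", "baseline", "alaam", "gof",
                                 "report")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage, n_before, n_after, msg = "") {
    log[[stage]] <<- list(n_before = n_before, n_after = n_after, msg = msg)
    message(sprintf("[%s] %d -> %d %s", stage, n_before, n_after, msg))
  }
  res <- list(config = config, log = NULL)

  pop <- simulate_population(config$generator)
  if ("simulate" %in% stages) {
    write_population(pop, config$out_dir)
    note("simulate", config$generator$n_households, pop$net$n_house,
         sprintf("(%d episodes)", nrow(pop$episodes)))
  }
  res$population <- pop
  net <- pop$net

  if ("network" %in% stages) {
    summ <- network_summary(net, seed = split_seed(config$seed, 21L))
    ed <- net$edges
    write.csv(data.frame(h1 = ed$h1, h2 = ed$h2,
                         same_region = ed$same_region,
                         shared_years = ed$shared_years,
                         n_shared_members = ed$n_shared_members),
              file.path(config$out_dir, "edges.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(summ),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    igraph::write_graph(as_igraph(net),
                        file.path(config$out_dir, "household_network.graphml"),
                        format = "graphml")
    note("network", net$n_house, summ$n_in_any_component, "households tied")
    res$summary <- summ
  }

  idx <- wealth_index(pop$assets$wave1, pop$assets$wave2)
  y_all <- sapply(c("any_change", "up", "down", "stable"),
                  function(m) household_outcome(idx, m))
  if ("wealth" %in% stages) {
    wtab <- data.frame(idx, y_anychange = y_all[, "any_change"],
                       y_up = y_all[, "up"], y_down = y_all[, "down"],
                       y_stable = y_all[, "stable"])
    write.csv(wtab, file.path(config$out_dir, "wealth.csv"),
              row.names = FALSE)
    note("wealth", nrow(idx), sum(complete.cases(idx)),
         "households with both waves")
  }
  res$wealth <- idx

  ineq <- regional_inequality(idx, pop$affiliations)
  Y <- regional_outcome(ineq, config$inequality_threshold)
  if ("inequality" %in% stages) {
    write.csv(cbind(ineq, Y = as.integer(Y)),
              file.path(config$out_dir, "inequality.csv"), row.names = FALSE)
    note("inequality", nrow(ineq), sum(Y), "regions with rising inequality")
  }
  res$inequality <- ineq; res$Y <- as.integer(Y)

  y <- household_outcome(idx, config$outcome_mode)
  m <- match(net$households, idx$household_id)
  y <- y[m]
  cov <- pop$covariates
  cov$baseline_quintile <- idx$q_w1[m]
  rc <- data.frame(region_id = ineq$region_id, inq_w1 = ineq$inq_w1)
  res$covariates <- cov

  if ("baseline" %in% stages) {
    dat <- data.frame(y = y, cov[setdiff(names(cov), "household_id")])
    dat <- dat[complete.cases(dat), ]
    bl <- baseline_logit(
      y ~ head_female + pension_eligible + mortality_any + n_nonresidents +
        I(n_nonresidents^2) + household_size + baseline_quintile +
        mean_tie_years, dat)
    rdat <- data.frame(Y = as.integer(Y), inq_w1 = ineq$inq_w1)
    blr <- baseline_logit(Y ~ inq_w1, rdat)
    ames <- do.call(rbind, lapply(
      c("head_female", "pension_eligible", "baseline_quintile",
        "n_nonresidents"), function(v) ame(bl, v)))
    prof <- nonresident_profile(bl)
    jsonlite::write_json(list(
      household = list(coef = as.list(coef(bl)), separation = bl$separation),
      region = list(coef = as.list(coef(blr)), separation = blr$separation)),
      file.path(config$out_dir, "baseline_fit.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(ames, file.path(config$out_dir, "ame.csv"), row.names = FALSE)
    write.csv(prof, file.path(config$out_dir, "nonresident_profile.csv"),
              row.names = FALSE)
    note("baseline", length(y), nrow(dat), "complete cases in household model")
    res$baseline <- list(household = bl, region = blr, ame = ames,
                         profile = prof)
  }

  if (any(c("alaam", "gof") %in% stages)) {
    eff <- if (is.null(config$effects))
      default_effects(covariates = setdiff(names(cov), "household_id"),
                      region_covariates = "inq_w1", poorest = TRUE)
    else alaam_effects(config$effects)
    fit <- alaam(y, net, eff, Y = as.integer(Y), covariates = cov,
                 region_covariates = rc, quintile = idx$q_w1[m],
                 control = config$control,
                 seed = split_seed(config$seed, 22L))
    jsonlite::write_json(list(
      theta = as.list(coef(fit)), se = as.list(fit$std_err),
      conv_t = as.list(fit$conv_t), converged = fit$converged,
      seed = fit$seed,
      settings = fit$control[c("phase1_n", "subphases", "phase2_base",
                               "phase3_n", "thin3", "steps")]),
      file.path(config$out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    note("alaam", sum(!is.na(y)), length(coef(fit)),
         sprintf("effects fitted, converged=%s", fit$converged))
    res$fit <- fit
    if ("gof" %in% stages) {
      write.csv(fit$gof, file.path(config$out_dir, "gof.csv"),
                row.names = FALSE)
      note("gof", nrow(fit$gof), sum(fit$gof$adequate, na.rm = TRUE),
           "statistics adequate")
    }
  }

  res$log <- log
  if ("report" %in% stages) {
    needed <- c("simulate", "network", "wealth", "inequality")
    if (!all(needed %in% names(log)))
      stop("report refused: missing stage counts for ",
           paste(setdiff(needed, names(log)), collapse = ", "))
    s <- res$summary
    if (!is.null(s) &&
        abs(s$mean_degree - 2 * s$n_edges / s$n_nodes) > 1e-12)
      stop("report refused: mean degree inconsistent with edge count")
    lines <- c("# Synthetic study report", "",
               sprintf("- households: %d, regions: %d",
                       net$n_house, net$n_region),
               if (!is.null(s))
                 sprintf("- network: %d ties, mean degree %.3f, clustering %.3f",
                         s$n_edges, s$mean_degree, s$global_clustering),
               sprintf("- households changing wealth quintile: %.1f%%",
                       100 * mean(y, na.rm = TRUE)),
               sprintf("- mean regional inequality: %.3f (wave 1), %.3f (wave 2)",
                       mean(ineq$inq_w1), mean(ineq$inq_w2)),
               sprintf("- regions with rising inequality (>= %.0f%%): %d of %d",
                       100 * config$inequality_threshold, sum(Y), nrow(ineq)),
               if (!is.null(res$fit))
                 sprintf("- ALAAM converged: %s; GOF adequate: %d/%d",
                         res$fit$converged,
                         sum(res$fit$gof$adequate, na.rm = TRUE),
                         nrow(res$fit$gof)),
               "", "## Stage log", "",
               vapply(names(log), function(nm)
                 sprintf("- %s: %d -> %d %s", nm, log[[nm]]$n_before,
                         log[[nm]]$n_after, log[[nm]]$msg), character(1)))
    writeLines(lines, file.path(config$out_dir, "report.md"))
  }
  res
}

#' Step-wise ALAAM specification ladder
#'
#' Fits a sequence of nested effect specifications from nodal covariates up
#' through structural, interaction, and cross-level configurations,
#' mirroring the ground-up model-building strategy.  The micro-macro link
#' may only enter once the cross-level interaction is present; violating
#' ladders are refused.
#'
#' @inheritParams alaam
#' @param rungs list of character vectors of effect terms, each rung
#'   cumulative over the previous; `NULL` uses the default six-rung ladder.
#' @return list of class `"alaam_ladder"`: `fits` (one [alaam()] per rung)
#'   and `comparison` (effects x rungs estimate table).
#' @export
ladder_fit <- function(y, net, Y, covariates = NULL,
                       region_covariates = NULL, quintile = NULL,
                       rungs = NULL, control = alaam_control(), seed = 1L) {
  if (is.null(rungs)) {
    covs <- if (is.null(covariates)) character() else
      setdiff(names(covariates), c("household_id", "n_nonresidents"))
    rungs <- list(
      c("h_density", "r_density", paste0("cov:", covs, recycle0 = TRUE),
        if (!is.null(covariates) && "n_nonresidents" %in% names(covariates))
          "external_ties",
        if (!is.null(region_covariates))
          paste0("rcov:", setdiff(names(region_covariates), "region_id"),
                 recycle0 = TRUE)),
      c("h_connectivity", "h_closure", "r_connectivity"),
      c("same_region_connectivity", "cross_region_connectivity",
        if (!is.null(covariates) && "n_nonresidents" %in% names(covariates))
          "external_ties_sq",
        "same_region_contagion", "cross_region_contagion"),
      c("r_cross_ties", "rr_contagion"),
      "cross_level",
      "micro_macro")
  }
  terms <- character(0)
  fits <- list()
  for (k in seq_along(rungs)) {
    terms <- c(terms, unlist(rungs[[k]]))
    if ("micro_macro" %in% terms && !"cross_level" %in% terms)
      stop("ladder violation: micro_macro requires cross_level first")
    eff <- alaam_effects(terms)
    fits[[k]] <- alaam(y, net, eff, Y = Y, covariates = covariates,
                       region_covariates = region_covariates,
                       quintile = quintile, control = control,
                       seed = split_seed(seed, 30L + k))
  }
  all_names <- unique(unlist(lapply(fits, function(f) names(coef(f)))))
  comparison <- sapply(fits, function(f) {
    th <- coef(f)[all_names]; names(th) <- all_names; th
  })
  colnames(comparison) <- paste0("rung", seq_along(fits))
  structure(list(fits = fits, comparison = comparison),
            class = "alaam_ladder")
}

#' @export
print.alaam_ladder <- function(x, ...) {
  cat("ALAAM specification ladder:", length(x$fits), "rungs\n")
  print(round(x$comparison, 3))
  invisible(x)
}
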