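#' In-silico perturbation analysis of a signalling network
#'
#' The package's main entry point. Starting from a bipartite species/reaction
#' network and a seed species, it (1) optionally extracts the seed-centred
#' subnetwork (strongly connected core plus weakly connected nodes, isolated
#' clusters removed), (2) simulates token-flow ensembles for a control
#' scenario and for down- and up-regulation of the seed (by default 100, 10
#' and 500 seed tokens at time zero; 500 runs over 20 time points each), and
#' (3) screens every species for a significant change of its mean token
#' level at the final time point via the two-sample t statistic.
#'
#' Scenario ensembles use distinct, reproducibly derived RNG seeds
#' (`rng_seed`, `rng_seed + 1`, `rng_seed + 2` for control, down, up), so a
#' single integer determines the whole analysis.
#'
#' @param net a [signaling_network()] (or a path to a GraphML file).
#' @param seed_species id of the species to perturb.
#' @param scenarios named numeric vector of seed token levels at time zero;
#'   must include `control` plus at least one of `down`, `up`.
#' @param n_runs,n_timepoints,source_tokens,modifier_threshold simulation
#'   parameters, see [spn_config()].
#' @param rng_seed integer seed for the whole analysis.
#' @param extract if `TRUE` (default), trim the network to the seed's
#'   subnetwork before simulating.
#' @param test an [test_config()] for the significance screen.
#' @return An object of class `spn_perturb`: a list with elements `network`
#'   (the simulated network), `extraction` (an `spn_extraction` or `NULL`),
#'   `roles`, `scenarios`, `summaries` (named list of `spn_trajectory`),
#'   `screens` (named list of `spn_screen`, one per non-control scenario),
#'   `table` ([results_table()] output when both `up` and `down` were run),
#'   and `call`.
#' @seealso [summary.spn_perturb()], [coef.spn_perturb()],
#'   [plot.spn_perturb()], [simulate.spn_perturb()]
#' @export
#' @examples
#' fit <- spn_perturb(crkl_motif(), "CRKL", n_runs = 50, rng_seed = 1)
#' fit
#' coef(fit)
spn_perturb <- function(net, seed_species,
                        scenarios = c(control = 100, down = 10, up = 500),
                        n_runs = 500, n_timepoints = 20, source_tokens = 100,
                        modifier_threshold = 1, rng_seed = 1,
                        extract = TRUE, test = test_config()) {
  cl <- match.call()
  if (is.character(net) && length(net) == 1) net <- read_graphml(net)
  stopifnot(inherits(net, "signaling_network"))
  if (!"control" %in% names(scenarios) || length(scenarios) < 2) {
    stop("`scenarios` must name a control level and at least one perturbation")
  }

  extraction <- NULL
  if (extract) {
    extraction <- extract_seed_subnetwork(net, seed_species)
    net <- extraction$subnetwork
  }
  roles <- assign_roles(net)

  summaries <- list()
  sc_names <- names(scenarios)
  offsets <- stats::setNames(seq_along(sc_names) - 1L,
                             c("control", setdiff(sc_names, "control")))
  for (sc in names(offsets)) {
    cfg <- spn_config(
      seed_species = seed_species, seed_tokens = scenarios[[sc]],
      n_runs = n_runs, n_timepoints = n_timepoints,
      source_tokens = source_tokens, rng_seed = rng_seed + offsets[[sc]],
      modifier_threshold = modifier_threshold
    )
    summaries[[sc]] <- simulate_ensemble(net, cfg, roles)
  }

  screens <- list()
  for (sc in setdiff(names(summaries), "control")) {
    screens[[sc]] <- screen_perturbation(summaries$control, summaries[[sc]],
                                         net = net, test = test)
  }
  tab <- if (all(c("up", "down") %in% names(screens))) {
    results_table(screens$up, screens$down)
  } else NULL

  structure(
    list(network = net, extraction = extraction, roles = roles,
         scenarios = scenarios, summaries = summaries, screens = screens,
         table = tab, test = test, call = cl),
    class = "spn_perturb"
  )
}

#' @export
print.spn_perturb <- function(x, ...) {
  cat("In-silico perturbation analysis (signalling Petri net)\n")
  cat(sprintf("  seed species: %s\n", x$summaries$control$config$seed_species))
  cat(sprintf("  network: %d species, %d reactions\n",
              nrow(x$network$species), nrow(x$network$reactions)))
  cat(sprintf("  scenarios (seed tokens at t=0): %s\n",
              paste(sprintf("%s=%g", names(x$scenarios), x$scenarios),
                    collapse = ", ")))
  cat(sprintf("  %d runs over %d time points per scenario\n",
              x$summaries$control$n_runs,
              ncol(x$summaries$control$mean) - 1L))
  for (sc in names(x$screens)) {
    s <- x$screens[[sc]]
    cat(sprintf("  %s-regulation: %d of %d reported species significant\n",
                sc, sum(s$significant & s$reported), sum(s$reported)))
  }
  invisible(x)
}

#' Summarise a perturbation analysis
#'
#' Prints the combined results table: per species the control, up- and
#' down-regulated mean token counts at the final time point and the absolute
#' t value with p value for each perturbation (small p values shown as
#' `"<0.001"`).
#'
#' @param object an `spn_perturb` fit.
#' @param formatted show display-style columns (default `TRUE`).
#' @param ... unused.
#' @return The (raw) results table, invisibly.
#' @export
summary.spn_perturb <- function(object, formatted = TRUE, ...) {
  print(object)
  if (!is.null(object$table)) {
    cat(sprintf(
      "\nMean tokens at the final time point and |t| (p) vs control:\n"))
    print(results_table(object$screens$up, object$screens$down,
                        formatted = formatted), row.names = FALSE)
    sig <- unique(unlist(lapply(object$screens, function(s)
      s$name[s$significant & s$reported])))
    cat(sprintf("\nSignificant in at least one scenario: %s\n",
                if (length(sig)) paste(sort(sig), collapse = ", ")
                else "none"))
  }
  invisible(object$table)
}

#' Extract the screening statistics of a perturbation fit
#'
#' @param object an `spn_perturb` fit.
#' @param ... unused.
#' @return Numeric matrix of signed t values, species x scenario.
#' @export
coef.spn_perturb <- function(object, ...) {
  scs <- names(object$screens)
  m <- sapply(object$screens, function(s) s$t_value)
  rownames(m) <- object$screens[[1]]$id
  colnames(m) <- paste0("t_", scs)
  m
}

#' @export
as.data.frame.spn_perturb <- function(x, ...) {
  if (is.null(x$table)) {
    stop("no combined table: fit both `up` and `down` scenarios")
  }
  x$table
}

#' Plot mean token trajectories of a perturbation fit
#'
#' One panel per scenario, mean token count against time for each species
#' (optionally only the significant ones, with the seed omissible since its
#' level is set by the scenario).
#'
#' @param x an `spn_perturb` fit.
#' @param which scenarios to draw (default all simulated).
#' @param species ids to draw; default the species significant in at least
#'   one scenario, or all when no screen flagged any.
#' @param exclude_seed drop the seed species from the panels.
#' @param log use a log-1p vertical scale.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.spn_perturb <- function(x, which = names(x$summaries), species = NULL,
                             exclude_seed = FALSE, log = FALSE, ...) {
  if (is.null(species)) {
    species <- unique(unlist(lapply(x$screens, function(s)
      s$id[s$significant & s$reported])))
    if (length(species) == 0) species <- rownames(x$summaries[[1]]$mean)
  }
  if (exclude_seed) {
    species <- setdiff(species, x$summaries$control$config$seed_species)
  }
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (sc in which) {
    mu <- t(x$summaries[[sc]]$mean[species, , drop = FALSE])
    y <- if (log) log1p(mu) else mu
    graphics::matplot(seq_len(nrow(y)) - 1L, y, type = "l", lty = 1,
                      xlab = "time point",
                      ylab = if (log) "log(1 + mean tokens)" else
                        "mean tokens",
                      main = sprintf("%s scenario", sc), ...)
    graphics::legend("topright", legend = species, lty = 1,
                     col = seq_along(species), cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Simulate fresh trajectories from a fitted perturbation analysis
#'
#' Draws `nsim` new stochastic runs of one scenario under the fitted
#' configuration, seeded from `seed`.
#'
#' @param object an `spn_perturb` fit.
#' @param nsim number of runs.
#' @param seed integer RNG seed (default: the fit's scenario seed).
#' @param scenario which scenario configuration to use.
#' @param ... unused.
#' @return List of `nsim` trajectory matrices (time x species).
#' @export
simulate.spn_perturb <- function(object, nsim = 1, seed = NULL,
                                 scenario = "control", ...) {
  cfg <- object$summaries[[scenario]]$config
  if (!is.null(seed)) cfg$rng_seed <- as.integer(seed)
  lapply(seq_len(nsim), function(i)
    simulate_run(object$network, cfg, run = i, roles = object$roles))
}
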