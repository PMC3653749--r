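#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one (YAML-serialisable)
#' object: the input network, the seed species, the scenario token levels,
#' the simulation parameters and the test parameters.
#'
#' @param network path to a GraphML file, or `NULL` when the network object
#'   is passed to [run_pipeline()] directly.
#' @param seed_species id of the species to perturb.
#' @param scenarios named list/vector of seed token levels at time zero.
#' @param n_runs,n_timepoints,source_tokens,modifier_threshold,rng_seed see
#'   [spn_config()].
#' @param alpha,critical_value,df_for_p,active_only see [test_config()].
#' @param extract trim to the seed subnetwork first, see [spn_perturb()].
#' @param out_dir directory where [run_pipeline()] writes its artefacts.
#' @param graphml_attrs attribute-name mapping for GraphML ingest, see
#'   [graphml_attrs()].
#' @return An object of class `spn_pipeline_config`.
#' @export
pipeline_config <- function(network = NULL, seed_species,
                            scenarios = list(control = 100, down = 10,
                                             up = 500),
                            n_runs = 500, n_timepoints = 20,
                            source_tokens = 100, modifier_threshold = 1,
                            rng_seed = 1, alpha = 0.05,
                            critical_value = 1.965, df_for_p = NULL,
                            active_only = TRUE, extract = TRUE,
                            out_dir = ".",
                            graphml_attrs = spnperturb::graphml_attrs()) {
  structure(
    list(network = network, seed_species = seed_species,
         scenarios = as.list(scenarios), n_runs = n_runs,
         n_timepoints = n_timepoints, source_tokens = source_tokens,
         modifier_threshold = modifier_threshold, rng_seed = rng_seed,
         alpha = alpha, critical_value = critical_value,
         df_for_p = df_for_p, active_only = active_only, extract = extract,
         out_dir = out_dir, graphml_attrs = graphml_attrs),
    class = "spn_pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file round-trips losslessly: `read_pipeline_config()` after
#' [write_pipeline_config()] reproduces the configuration.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @return `write_pipeline_config()`: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "spn_pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_summary_csv <- function(summary, path) {
  mu <- summary$mean
  va <- summary$variance
  long <- data.frame(
    species_id = rep(rownames(mu), times = ncol(mu)),
    time = rep(0:(ncol(mu) - 1L), each = nrow(mu)),
    mean = as.vector(mu),
    variance = as.vector(va),
    n_runs = summary$n_runs,
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Run the full perturbation pipeline and write its artefacts
#'
#' Drives the whole analysis from a configuration: load (or take) the
#' network, extract the seed subnetwork, simulate every scenario ensemble,
#' screen for significant species, and write the artefact set to
#' `config$out_dir`: the extracted network (`subnetwork.graphml`), an
#' extraction report (`extraction.json`), one long-format means CSV per
#' scenario (`means_<scenario>.csv`), raw and formatted results tables
#' (`results_table.csv`, `results_table_formatted.csv`), the trajectory
#' export of the significant species (`significant_profiles.csv`), and a
#' machine-readable run manifest (`manifest.json`: parameters, seeds,
#' package version, file list) from which the run can be reproduced.
#'
#' @param config a [pipeline_config()].
#' @param net optional [signaling_network()] overriding `config$network`.
#' @return The underlying [spn_perturb()] fit, invisibly, with the artefact
#'   paths attached as attribute `"artifacts"`.
#' @export
run_pipeline <- function(config, net = NULL) {
  stopifnot(inherits(config, "spn_pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[spnperturb] %s (%.2fs)", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  if (is.null(net)) {
    if (is.null(config$network)) {
      stop("pipeline stage 'load' failed: no network given", call. = FALSE)
    }
    net <- stage("load network", read_graphml(
      config$network, attrs = do.call(graphml_attrs, config$graphml_attrs)))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)

  fit <- stage("simulate and screen", spn_perturb(
    net, config$seed_species,
    scenarios = unlist(config$scenarios),
    n_runs = config$n_runs, n_timepoints = config$n_timepoints,
    source_tokens = config$source_tokens,
    modifier_threshold = config$modifier_threshold,
    rng_seed = config$rng_seed, extract = config$extract,
    test = test_config(alpha = config$alpha,
                       critical_value = config$critical_value,
                       df_for_p = config$df_for_p,
                       active_only = config$active_only)
  ))

  artifacts <- character()
  stage("write artefacts", {
    write_graphml(fit$network, p("subnetwork.graphml"))
    artifacts <- c(artifacts, p("subnetwork.graphml"))
    if (!is.null(fit$extraction)) {
      jsonlite::write_json(
        list(seed = fit$extraction$seed,
             core_ids = fit$extraction$core_ids,
             augmented_ids = fit$extraction$augmented_ids,
             removed_ids = fit$extraction$removed_ids,
             counts = list(core = length(fit$extraction$core_ids),
                           augmented = length(fit$extraction$augmented_ids),
                           removed = length(fit$extraction$removed_ids))),
        p("extraction.json"), auto_unbox = TRUE, pretty = TRUE)
      artifacts <- c(artifacts, p("extraction.json"))
    }
    for (sc in names(fit$summaries)) {
      f <- p(sprintf("means_%s.csv", sc))
      write_summary_csv(fit$summaries[[sc]], f)
      artifacts <- c(artifacts, f)
    }
    if (!is.null(fit$table)) {
      utils::write.csv(fit$table, p("results_table.csv"), row.names = FALSE)
      utils::write.csv(results_table(fit$screens$up, fit$screens$down,
                                     formatted = TRUE),
                       p("results_table_formatted.csv"), row.names = FALSE)
      artifacts <- c(artifacts, p("results_table.csv"),
                     p("results_table_formatted.csv"))
    }
    sig <- unique(unlist(lapply(fit$screens, function(s)
      s$id[s$significant & s$reported])))
    for (sc in names(fit$summaries)) {
      f <- p(sprintf("significant_profiles_%s.csv", sc))
      export_profiles(fit$summaries[[sc]], species = sig, path = f)
      artifacts <- c(artifacts, f)
    }
  })

  manifest <- list(
    package = "spnperturb",
    version = as.character(utils::packageVersion("spnperturb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    artifacts = basename(artifacts),
    n_species = nrow(fit$network$species),
    n_reactions = nrow(fit$network$reactions),
    significant = lapply(fit$screens, function(s)
      s$id[s$significant & s$reported])
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  artifacts <- c(artifacts, p("manifest.json"))

  attr(fit, "artifacts") <- artifacts
  invisible(fit)
}

#' Export mean token trajectories as long-format CSV
#'
#' Writes `species_id, time, mean` rows for the selected species. The
#' `every_10th` sampling mode reproduces the reporting convention of taking
#' every 10th species after sorting by mean token level at the final time
#' point (ranks 1, 11, 21, ...); `exclude` drops species (e.g. the seed,
#' whose level is set by the scenario) before sampling.
#'
#' @param summary an `spn_trajectory`.
#' @param species ids to export; `NULL` for all. An empty selection writes
#'   a header-only file.
#' @param path output CSV path, or `NULL` to only return the data.
#' @param every_10th apply the rank-sampling mode described above.
#' @param exclude species ids to drop first.
#' @return The exported data.frame, invisibly.
#' @export
export_profiles <- function(summary, species = NULL, path = NULL,
                            every_10th = FALSE, exclude = NULL) {
  stopifnot(inherits(summary, "spn_trajectory"))
  mu <- summary$mean
  ids <- rownames(mu)
  if (!is.null(species)) ids <- intersect(ids, species)
  if (!is.null(exclude)) ids <- setdiff(ids, exclude)
  if (every_10th && length(ids) > 0) {
    fin <- mu[ids, ncol(mu)]
    ids <- ids[order(-fin)][seq(1, length(ids), by = 10)]
  }
  mu <- mu[ids, , drop = FALSE]
  out <- data.frame(
    species_id = rep(ids, times = ncol(mu)),
    time = rep(0:(ncol(mu) - 1L), each = length(ids)),
    mean = as.vector(mu),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
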