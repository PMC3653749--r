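#' Strongly connected core around a seed species
#'
#' Returns the node set (species and reactions) of the strongly connected
#' component of the directed bipartite graph that contains the seed — every
#' node in the set reaches every other along directed paths. Strong
#' connectivity is computed on the bipartite graph with reaction nodes
#' included: a species-only projection would change the components. If the
#' seed lies on no directed cycle the core is the singleton `{seed}`.
#'
#' @param net a [signaling_network()].
#' @param seed a species id present in `net`.
#' @return Character vector of node ids (species and reaction ids).
#' @export
strongly_connected_core <- function(net, seed) {
  stopifnot(inherits(net, "signaling_network"))
  if (!seed %in% node_ids(net)) {
    stop(sprintf("seed '%s' is not a node of the network", seed))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  keep <- comp$membership == comp$membership[[seed]]
  igraph::V(g)$name[keep]
}

#' Augment a core with all weakly connected nodes
#'
#' Adds every node with a directed connection to the core in at least one
#' direction: the union of the core, its ancestors and its descendants.
#' Nodes with no directed path to or from the core (isolated clusters, which
#' cannot affect or be affected by the core) are excluded.
#'
#' @param net a [signaling_network()].
#' @param core non-empty character vector of node ids.
#' @return Character vector of node ids: `core` plus its ancestors and
#'   descendants.
#' @export
augment_weakly_connected <- function(net, core) {
  stopifnot(inherits(net, "signaling_network"), length(core) > 0)
  missing <- setdiff(core, node_ids(net))
  if (length(missing) > 0) {
    stop(sprintf("core ids not in network: %s",
                 paste(missing, collapse = ", ")))
  }
  g <- as_igraph(net)
  reach <- lapply(core, function(v) {
    c(igraph::subcomponent(g, v, mode = "out")$name,
      igraph::subcomponent(g, v, mode = "in")$name)
  })
  unique(c(core, unlist(reach)))
}

#' Extract the seed-centred subnetwork
#'
#' Reproduces the trimming used to carve a seed molecule's subnetwork out of
#' a larger map: (1) the strongly connected core containing the seed, (2)
#' augmentation with all nodes weakly connected to that core (ancestors and
#' descendants), and (3) removal of everything else — isolated clusters and
#' pathways that can neither affect nor be affected by perturbation of the
#' seed. The subnetwork is the induced subgraph on the retained nodes.
#' Reactions left dangling by the cut (losing all reactant-or-modifier inputs
#' or all products) are flagged in the attached validation report, not
#' silently dropped.
#'
#' @param net a [signaling_network()].
#' @param seed a species id present in `net`.
#' @return An object of class `spn_extraction`: a list with elements
#'   `subnetwork` ([signaling_network()]), `core_ids`, `augmented_ids`
#'   (weakly connected additions, disjoint from `core_ids`), `removed_ids`,
#'   `seed`, and `report` (the validation report of the subnetwork).
#' @export
extract_seed_subnetwork <- function(net, seed) {
  core <- strongly_connected_core(net, seed)
  kept <- augment_weakly_connected(net, core)
  removed <- setdiff(node_ids(net), kept)
  sub <- induced_network(net, kept)
  report <- validate_network(sub)
  # reactions the cut stripped of all reactants or all products
  for (r in sub$reactions$id) {
    lost_re <- any(net$edges$kind == "reactant" & net$edges$target == r) &&
      !any(sub$edges$kind == "reactant" & sub$edges$target == r)
    lost_pr <- any(net$edges$kind == "product" & net$edges$source == r) &&
      !any(sub$edges$kind == "product" & sub$edges$source == r)
    if (lost_re) {
      report <- rbind(report, violation(
        "reaction_lost_reactants",
        sprintf("reaction '%s' lost every reactant place in the cut", r), r))
    }
    if (lost_pr) {
      report <- rbind(report, violation(
        "reaction_lost_products",
        sprintf("reaction '%s' lost every product place in the cut", r), r))
    }
  }
  structure(
    list(
      subnetwork = sub,
      core_ids = core,
      augmented_ids = setdiff(kept, core),
      removed_ids = removed,
      seed = seed,
      report = report
    ),
    class = "spn_extraction"
  )
}

#' @export
print.spn_extraction <- function(x, ...) {
  n_sp <- nrow(x$subnetwork$species)
  cat(sprintf("Seed-centred subnetwork extraction (seed: %s)\n", x$seed))
  cat(sprintf("  core (strongly connected with seed): %d nodes\n",
              length(x$core_ids)))
  cat(sprintf("  weakly connected additions:          %d nodes\n",
              length(x$augmented_ids)))
  cat(sprintf("  removed (isolated from seed):        %d nodes\n",
              length(x$removed_ids)))
  cat(sprintf("  subnetwork: %d species, %d reactions\n",
              n_sp, nrow(x$subnetwork$reactions)))
  if (nrow(x$report) > 0) {
    cat(sprintf("  %d validation flag(s) on the cut, see $report\n",
                nrow(x$report)))
  }
  invisible(x)
}
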