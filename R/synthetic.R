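#' Generate a random signalling network with planted ground truth
#'
#' Emulates the structure the analysis assumes in a seed-centred signalling
#' map: a designated seed species inside a planted strongly connected core
#' (a species cycle threaded through reactions), upstream source species that
#' feed the core, downstream species and sinks fed from it, optional modifier
#' (catalysis) edges, and optionally a planted isolated component with no
#' directed connection to the rest — the material the extraction step must
#' remove. Construction is layered (upstream -> core -> downstream, acyclic
#' within layers), so the planted core is provably the exact strongly
#' connected component of the seed and the planted isolated nodes are exactly
#' the nodes unreachable to/from it; both are returned as ground truth for
#' oracle tests.
#'
#' @param n_species total number of species (at least 2).
#' @param n_reactions target number of reactions; raised to the construction
#'   minimum when too small (at least 1).
#' @param p_modifier probability that a reaction receives a modifier edge
#'   from a structurally safe species.
#' @param p_inhibit probability that such a modifier is inhibiting rather
#'   than activating.
#' @param core_cycle_len number of species in the planted cycle through the
#'   seed; 0 or 1 leaves the seed outside any cycle (singleton core).
#' @param n_isolated number of species in the planted isolated component
#'   (a chain; 0 for none).
#' @param rng_seed integer seed; the same seed reproduces the same network.
#' @return A list with elements `network` (a validated
#'   [signaling_network()]) and `truth`: `seed`, `core_species`,
#'   `core_nodes` (species and reaction ids of the seed's strongly connected
#'   component), `isolated_species`, `isolated_nodes`, `upstream_species`,
#'   `downstream_species`.
#' @export
generate_network <- function(n_species, n_reactions, p_modifier = 0.1,
                             p_inhibit = 0, core_cycle_len = 3,
                             n_isolated = 0, rng_seed = 1) {
  stopifnot(n_species >= 2, n_reactions >= 1,
            p_modifier >= 0, p_modifier <= 1,
            p_inhibit >= 0, p_inhibit <= 1,
            core_cycle_len >= 0, n_isolated >= 0)
  n_core <- max(1L, as.integer(core_cycle_len))
  if (n_core + n_isolated > n_species) {
    stop("infeasible: core_cycle_len + n_isolated exceeds n_species")
  }
  n_free <- n_species - n_core - n_isolated

  with_preserved_rng({
    set.seed(rng_seed)

    # guarantee >= 1 source and >= 1 sink whenever the species budget allows
    if (n_free >= 2) {
      n_up <- 1L + stats::rbinom(1, n_free - 2L, 0.5)
      n_down <- n_free - n_up
    } else {
      n_up <- n_free
      n_down <- 0L
    }

    core_sp <- paste0("C", seq_len(n_core))
    up_sp <- if (n_up > 0) paste0("U", seq_len(n_up)) else character()
    down_sp <- if (n_down > 0) paste0("D", seq_len(n_down)) else character()
    iso_sp <- if (n_isolated > 0) paste0("I", seq_len(n_isolated)) else
      character()
    seed_id <- core_sp[1]

    edges <- list()
    rx_ids <- character()
    add_rx <- function(id, reactant, product) {
      rx_ids <<- c(rx_ids, id)
      edges[[length(edges) + 1]] <<- data.frame(
        source = c(reactant, id), target = c(id, product),
        kind = c("reactant", "product"), sign = "activating",
        stringsAsFactors = FALSE)
    }

    core_rx <- character()
    if (n_core >= 2) {
      for (j in seq_len(n_core)) {
        rid <- paste0("cr", j)
        core_rx <- c(core_rx, rid)
        add_rx(rid, core_sp[j], core_sp[if (j == n_core) 1L else j + 1L])
      }
    }
    # upstream DAG: U_i feeds a later upstream species or the core
    for (i in seq_len(n_up)) {
      pool <- c(if (i < n_up) up_sp[(i + 1):n_up], core_sp)
      add_rx(paste0("ur", i), up_sp[i], sample(pool, 1))
    }
    # downstream DAG: D_i is fed from the core or an earlier downstream
    for (i in seq_len(n_down)) {
      pool <- c(core_sp, if (i > 1) down_sp[seq_len(i - 1)])
      add_rx(paste0("dr", i), sample(pool, 1), down_sp[i])
    }
    if (n_isolated >= 2) {
      for (i in seq_len(n_isolated - 1L)) {
        add_rx(paste0("ir", i), iso_sp[i], iso_sp[i + 1L])
      }
    }

    # top up to the requested reaction count with SCC-preserving extras:
    # upstream->upstream (forward), upstream->core, core->downstream,
    # downstream->downstream (forward)
    extra_pairs <- list()
    if (n_up >= 2) {
      for (i in seq_len(n_up - 1)) for (j in (i + 1):n_up) {
        extra_pairs[[length(extra_pairs) + 1]] <- c(up_sp[i], up_sp[j])
      }
    }
    for (u in up_sp) for (cc in core_sp) {
      extra_pairs[[length(extra_pairs) + 1]] <- c(u, cc)
    }
    for (cc in core_sp) for (d in down_sp) {
      extra_pairs[[length(extra_pairs) + 1]] <- c(cc, d)
    }
    if (n_down >= 2) {
      for (i in seq_len(n_down - 1)) for (j in (i + 1):n_down) {
        extra_pairs[[length(extra_pairs) + 1]] <- c(down_sp[i], down_sp[j])
      }
    }
    n_extra <- max(0L, as.integer(n_reactions) - length(rx_ids))
    if (n_extra > 0 && length(extra_pairs) > 0) {
      picks <- sample.int(length(extra_pairs), min(n_extra,
                                                   length(extra_pairs)),
                          replace = FALSE)
      for (q in seq_along(picks)) {
        pr <- extra_pairs[[picks[q]]]
        add_rx(paste0("xr", q), pr[1], pr[2])
      }
    }

    # modifiers from structurally safe species (cannot enlarge the seed SCC):
    # upstream reactions may only be modified by strictly earlier upstream
    # species; everything in or below the core by any upstream species
    for (rid in rx_ids) {
      if (stats::runif(1) >= p_modifier) next
      if (grepl("^ir", rid)) next
      if (grepl("^ur", rid)) {
        i <- as.integer(sub("^ur", "", rid))
        pool <- if (i > 1) up_sp[seq_len(i - 1)] else character()
      } else {
        pool <- up_sp
      }
      if (length(pool) == 0) next
      sgn <- if (stats::runif(1) < p_inhibit) "inhibiting" else "activating"
      edges[[length(edges) + 1]] <- data.frame(
        source = sample(pool, 1), target = rid, kind = "modifier",
        sign = sgn, stringsAsFactors = FALSE)
    }

    species <- data.frame(id = c(core_sp, up_sp, down_sp, iso_sp),
                          stringsAsFactors = FALSE)
    reactions <- data.frame(id = rx_ids, stringsAsFactors = FALSE)
    net <- signaling_network(species, reactions, do.call(rbind, edges))

    truth <- list(
      seed = seed_id,
      core_species = if (n_core >= 2) core_sp else seed_id,
      core_nodes = if (n_core >= 2) c(core_sp, core_rx) else seed_id,
      isolated_species = iso_sp,
      isolated_nodes = c(iso_sp, if (n_isolated >= 2)
        paste0("ir", seq_len(n_isolated - 1L)) else character()),
      upstream_species = up_sp,
      downstream_species = down_sp
    )
    list(network = net, truth = truth)
  })
}

#' Six-species seed-motif fixture
#'
#' A fixed miniature of a seed-centred signalling subnetwork, with node
#' labels borrowed from the CRKL neighbourhood in rheumatoid-arthritis
#' signalling: the kinase ABL1 catalyses (as an activating modifier, without
#' being consumed) the feedback reaction that re-activates the seed CRKL;
#' token mass flows CRKL -> PXN -> RAPGEF1, from where it branches to the
#' sinks RHOQ and RAP1B and feeds back to CRKL. The feedback makes the
#' seed's strongly connected core non-trivial
#' (CRKL -> PXN -> RAPGEF1 -> CRKL); ABL1 is the single source and RHOQ and
#' RAP1B the two sinks. All species are annotated `active`.
#'
#' @return A validated [signaling_network()] with seed species `"CRKL"`.
#' @export
crkl_motif <- function() {
  species <- data.frame(
    id = c("ABL1", "CRKL", "PXN", "RAPGEF1", "RHOQ", "RAP1B"),
    state = "active", stringsAsFactors = FALSE
  )
  reactions <- data.frame(
    id = c("r_crkl_pxn", "r_pxn_rapgef1", "r_rapgef1_rhoq",
           "r_rapgef1_rap1b", "r_feedback"),
    label = c("CRKL->PXN", "PXN->RAPGEF1", "RAPGEF1->RHOQ",
              "RAPGEF1->RAP1B", "RAPGEF1->CRKL (ABL1-catalysed)"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    source = c("CRKL", "r_crkl_pxn",
               "PXN", "r_pxn_rapgef1",
               "RAPGEF1", "r_rapgef1_rhoq",
               "RAPGEF1", "r_rapgef1_rap1b",
               "RAPGEF1", "r_feedback", "ABL1"),
    target = c("r_crkl_pxn", "PXN",
               "r_pxn_rapgef1", "RAPGEF1",
               "r_rapgef1_rhoq", "RHOQ",
               "r_rapgef1_rap1b", "RAP1B",
               "r_feedback", "CRKL", "r_feedback"),
    kind = c("reactant", "product", "reactant", "product", "reactant",
             "product", "reactant", "product", "reactant", "product",
             "modifier"),
    sign = "activating",
    stringsAsFactors = FALSE
  )
  signaling_network(species, reactions, edges)
}

#' Linear chain fixture
#'
#' A species-reaction chain `S1 -> r1 -> S2 -> ... -> Sn` (labelled `A`,
#' `B`, ... for short chains): the substrate for exhaustive Markov-chain
#' enumeration oracles, whose state space stays enumerable for small token
#' counts. The first species is the single source, the last the single sink.
#'
#' @param length number of species (at least 2).
#' @return A validated [signaling_network()].
#' @export
chain_network <- function(length) {
  stopifnot(length >= 2)
  sp <- if (length <= 26) LETTERS[seq_len(length)] else
    paste0("S", seq_len(length))
  rx <- paste0("r", seq_len(length - 1))
  edges <- do.call(rbind, lapply(seq_len(length - 1), function(i) {
    data.frame(source = c(sp[i], rx[i]), target = c(rx[i], sp[i + 1]),
               kind = c("reactant", "product"), sign = "activating",
               stringsAsFactors = FALSE)
  }))
  signaling_network(data.frame(id = sp), data.frame(id = rx), edges)
}
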