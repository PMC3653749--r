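#' Construct a bipartite signalling network
#'
#' A signalling network is a directed bipartite graph in the Petri-net sense:
#' species are places holding tokens, reactions are transitions moving them.
#' Edges are typed after the SBML reaction roles: `reactant` edges run
#' species -> reaction, `product` edges run reaction -> species, and
#' `modifier` edges run species -> reaction and gate the transition without
#' consuming tokens (catalysis, e.g. a kinase enabling a phosphorylation).
#' Modifier edges carry a `sign`: `activating` modifiers must hold tokens for
#' the reaction to fire, `inhibiting` modifiers block it when they do.
#'
#' A molecule that the source map distinguishes by activation state may appear
#' as two species nodes sharing a `name`; no merging is performed.
#'
#' @param species data.frame with columns `id` (unique character), optionally
#'   `name` (display label, defaults to `id`) and `state`
#'   (`"active"`, `"inactive"` or `"unspecified"`; default `"unspecified"`).
#' @param reactions data.frame with column `id` and optionally `label`.
#' @param edges data.frame with columns `source`, `target`, `kind`
#'   (`"reactant"`, `"product"` or `"modifier"`) and optionally `sign`
#'   (`"activating"` or `"inhibiting"`, modifiers only; default
#'   `"activating"`).
#' @param check if `TRUE` (default), structural violations raise an error;
#'   see [validate_network()] for a non-throwing report.
#' @return An object of class `signaling_network`: a list with normalised
#'   `species`, `reactions` and `edges` data frames.
#' @seealso [validate_network()], [read_graphml()], [write_graphml()]
#' @export
#' @examples
#' net <- signaling_network(
#'   species   = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = "r1"),
#'   edges     = data.frame(source = c("A", "r1"), target = c("r1", "B"),
#'                          kind = c("reactant", "product"))
#' )
#' net
signaling_network <- function(species, reactions, edges, check = TRUE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)

  if (nrow(species) > 0 && is.null(species$id)) {
    stop("`species` must have an `id` column")
  }
  if (nrow(reactions) > 0 && is.null(reactions$id)) {
    stop("`reactions` must have an `id` column")
  }
  species <- data.frame(
    id = as.character(species$id %||% character()),
    name = as.character(species$name %||% species$id %||% character()),
    state = as.character(species$state %||%
                           rep("unspecified", nrow(species))),
    stringsAsFactors = FALSE
  )
  species$state[is.na(species$state) | species$state == ""] <- "unspecified"
  reactions <- data.frame(
    id = as.character(reactions$id %||% character()),
    label = as.character(reactions$label %||% reactions$id %||% character()),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) > 0 &&
      (is.null(edges$source) || is.null(edges$target) || is.null(edges$kind))) {
    stop("`edges` must have `source`, `target` and `kind` columns")
  }
  edges <- data.frame(
    source = as.character(edges$source %||% character()),
    target = as.character(edges$target %||% character()),
    kind = as.character(edges$kind %||% character()),
    sign = as.character(edges$sign %||% rep("activating", nrow(edges))),
    stringsAsFactors = FALSE
  )
  edges$sign[is.na(edges$sign) | edges$sign == ""] <- "activating"

  net <- structure(
    list(species = species, reactions = reactions, edges = edges),
    class = "signaling_network"
  )
  if (check) {
    rep <- validate_network(net)
    hard <- rep[rep$kind %in% c(
      "duplicate_id", "unknown_node", "unknown_edge_kind", "unknown_sign",
      "nonbipartite_edge", "bad_edge_direction", "bad_state"
    ), , drop = FALSE]
    if (nrow(hard) > 0) {
      stop(network_validation_error(hard))
    }
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

network_validation_error <- function(report) {
  structure(
    class = c("spn_validation_error", "error", "condition"),
    list(
      message = paste0(
        "invalid signalling network:\n",
        paste0("  [", report$kind, "] ", report$message, collapse = "\n")
      ),
      call = NULL,
      report = report
    )
  )
}

violation <- function(kind, message, id = NA_character_) {
  data.frame(kind = kind, id = id, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a signalling network
#'
#' Checks every structural invariant and returns a report instead of raising:
#' unique node ids, bipartiteness (no species-species or reaction-reaction
#' edge), edge direction by kind (reactant and modifier edges species ->
#' reaction, product edges reaction -> species), known edge kinds and signs,
#' and that every reaction has at least one reactant-or-modifier input and at
#' least one product output.
#'
#' @param net a [signaling_network()].
#' @return A data.frame with columns `kind`, `id` and `message`; zero rows
#'   when every invariant holds.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  sp <- net$species; rx <- net$reactions; ed <- net$edges
  out <- list()

  dup <- c(sp$id[duplicated(sp$id)], rx$id[duplicated(rx$id)],
           intersect(sp$id, rx$id))
  for (d in unique(dup)) {
    out[[length(out) + 1]] <-
      violation("duplicate_id", sprintf("node id '%s' is not unique", d), d)
  }
  bad_state <- sp$id[!sp$state %in% c("active", "inactive", "unspecified")]
  for (s in bad_state) {
    out[[length(out) + 1]] <-
      violation("bad_state", sprintf("species '%s' has unknown state", s), s)
  }

  for (i in seq_len(nrow(ed))) {
    s <- ed$source[i]; t <- ed$target[i]; k <- ed$kind[i]
    eid <- sprintf("%s->%s", s, t)
    s_sp <- s %in% sp$id; s_rx <- s %in% rx$id
    t_sp <- t %in% sp$id; t_rx <- t %in% rx$id
    if (!s_sp && !s_rx) {
      out[[length(out) + 1]] <-
        violation("unknown_node", sprintf("edge %s: unknown source", eid), eid)
      next
    }
    if (!t_sp && !t_rx) {
      out[[length(out) + 1]] <-
        violation("unknown_node", sprintf("edge %s: unknown target", eid), eid)
      next
    }
    if ((s_sp && t_sp) || (s_rx && t_rx)) {
      out[[length(out) + 1]] <- violation(
        "nonbipartite_edge",
        sprintf("edge %s joins two %s nodes", eid,
                if (s_sp) "species" else "reaction"), eid)
      next
    }
    if (!k %in% c("reactant", "product", "modifier")) {
      out[[length(out) + 1]] <- violation(
        "unknown_edge_kind", sprintf("edge %s has unknown kind '%s'", eid, k),
        eid)
      next
    }
    ok_dir <- switch(k,
      reactant = s_sp && t_rx,
      modifier = s_sp && t_rx,
      product = s_rx && t_sp
    )
    if (!ok_dir) {
      out[[length(out) + 1]] <- violation(
        "bad_edge_direction",
        sprintf("%s edge %s runs in the wrong direction", k, eid), eid)
    }
    if (!ed$sign[i] %in% c("activating", "inhibiting")) {
      out[[length(out) + 1]] <- violation(
        "unknown_sign", sprintf("edge %s has unknown sign '%s'", eid,
                                ed$sign[i]), eid)
    }
  }

  # reaction in/out degree (only meaningful if edges are structurally sound)
  for (r in rx$id) {
    n_in <- sum(ed$target == r & ed$kind %in% c("reactant", "modifier"))
    n_out <- sum(ed$source == r & ed$kind == "product")
    if (n_in == 0) {
      out[[length(out) + 1]] <- violation(
        "reaction_no_input",
        sprintf("reaction '%s' has no reactant or modifier edge", r), r)
    }
    if (n_out == 0) {
      out[[length(out) + 1]] <- violation(
        "reaction_no_product",
        sprintf("reaction '%s' has no product edge", r), r)
    }
  }

  if (length(out) == 0) {
    data.frame(kind = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf(
    "Signalling network: %d species, %d reactions, %d edges\n",
    nrow(x$species), nrow(x$reactions), nrow(x$edges)))
  kinds <- table(factor(x$edges$kind,
                        levels = c("reactant", "product", "modifier")))
  cat(sprintf("  edges: %d reactant, %d product, %d modifier\n",
              kinds[["reactant"]], kinds[["product"]], kinds[["modifier"]]))
  st <- table(factor(x$species$state,
                     levels = c("active", "inactive", "unspecified")))
  if (st[["active"]] + st[["inactive"]] > 0) {
    cat(sprintf("  species states: %d active, %d inactive, %d unspecified\n",
                st[["active"]], st[["inactive"]], st[["unspecified"]]))
  }
  invisible(x)
}

#' Convert a signalling network to an igraph object
#'
#' Vertices carry `name` (the node id), `nodekind` (`"species"` or
#' `"reaction"`), `label` and `state`; edges carry `edgekind` and `sign`.
#'
#' @param net a [signaling_network()].
#' @return An igraph directed graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  vertices <- data.frame(
    name = c(net$species$id, net$reactions$id),
    nodekind = c(rep("species", nrow(net$species)),
                 rep("reaction", nrow(net$reactions))),
    label = c(net$species$name, net$reactions$label),
    state = c(net$species$state, rep("", nrow(net$reactions))),
    stringsAsFactors = FALSE
  )
  ed <- net$edges
  if (nrow(ed) == 0) {
    ed <- data.frame(from = character(), to = character(),
                     edgekind = character(), sign = character())
  } else {
    ed <- data.frame(from = ed$source, to = ed$target, edgekind = ed$kind,
                     sign = ed$sign, stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vertices)
}

node_ids <- function(net) c(net$species$id, net$reactions$id)

induced_network <- function(net, keep_ids) {
  sp <- net$species[net$species$id %in% keep_ids, , drop = FALSE]
  rx <- net$reactions[net$reactions$id %in% keep_ids, , drop = FALSE]
  ed <- net$edges[net$edges$source %in% keep_ids &
                    net$edges$target %in% keep_ids, , drop = FALSE]
  rownames(sp) <- rownames(rx) <- rownames(ed) <- NULL
  structure(list(species = sp, reactions = rx, edges = ed),
            class = "signaling_network")
}
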