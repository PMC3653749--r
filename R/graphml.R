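#' GraphML attribute mapping
#'
#' Names of the GraphML node/edge attributes that encode the bipartite
#' structure. Foreign GraphML dialects (different attribute names for the
#' same concepts) can be adapted by overriding entries, without code change.
#'
#' @param nodekind node attribute holding `"species"` / `"reaction"`.
#' @param state node attribute holding `"active"` / `"inactive"` (optional in
#'   the file; absent means `"unspecified"`).
#' @param label node attribute holding the display label (optional).
#' @param edgekind edge attribute holding `"reactant"` / `"product"` /
#'   `"modifier"`.
#' @param sign edge attribute holding `"activating"` / `"inhibiting"`
#'   (optional; absent means `"activating"`).
#' @return A named list of attribute names.
#' @export
graphml_attrs <- function(nodekind = "nodekind", state = "state",
                          label = "label", edgekind = "edgekind",
                          sign = "sign") {
  list(nodekind = nodekind, state = state, label = label,
       edgekind = edgekind, sign = sign)
}

#' Read a signalling network from GraphML
#'
#' Loads a directed bipartite species/reaction network. Node ids are taken
#' from the igraph `name` attribute when present, else from the GraphML node
#' ids, and are preserved verbatim. Structural violations (an edge joining
#' two species, an unknown edge kind, duplicate ids) raise a structured error
#' of class `spn_validation_error` whose `report` field names the offending
#' nodes/edges; soft violations (a reaction with no product) are attached as
#' the `"validation"` attribute of the returned network.
#'
#' @param path path to a GraphML file.
#' @param attrs attribute-name mapping, see [graphml_attrs()].
#' @return A validated [signaling_network()].
#' @export
read_graphml <- function(path, attrs = graphml_attrs()) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  g <- igraph::read_graph(path, format = "graphml")

  n <- igraph::vcount(g)
  va <- igraph::vertex_attr_names(g)
  ids <- if ("name" %in% va) igraph::V(g)$name else
    if ("id" %in% va) igraph::vertex_attr(g, "id") else as.character(seq_len(n))
  getv <- function(at, default) {
    if (at %in% va) {
      v <- as.character(igraph::vertex_attr(g, at))
      v[is.na(v) | v == ""] <- default
      v
    } else rep(default, n)
  }
  if (!attrs$nodekind %in% va && n > 0) {
    stop(network_validation_error(violation(
      "missing_attribute",
      sprintf("node attribute '%s' not present in '%s'",
              attrs$nodekind, path))))
  }
  kind <- getv(attrs$nodekind, "")
  bad <- ids[!kind %in% c("species", "reaction")]
  if (length(bad) > 0) {
    stop(network_validation_error(do.call(rbind, lapply(bad, function(b)
      violation("unknown_node_kind",
                sprintf("node '%s' has unknown kind", b), b)))))
  }
  state <- getv(attrs$state, "unspecified")
  label <- getv(attrs$label, "")

  ne <- igraph::ecount(g)
  ea <- igraph::edge_attr_names(g)
  if (!attrs$edgekind %in% ea && ne > 0) {
    stop(network_validation_error(violation(
      "missing_attribute",
      sprintf("edge attribute '%s' not present in '%s'",
              attrs$edgekind, path))))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  gete <- function(at, default) {
    if (at %in% ea) {
      v <- as.character(igraph::edge_attr(g, at))
      v[is.na(v) | v == ""] <- default
      v
    } else rep(default, ne)
  }

  is_sp <- kind == "species"
  species <- data.frame(id = ids[is_sp], name = label[is_sp],
                        state = state[is_sp], stringsAsFactors = FALSE)
  species$name[species$name == ""] <- species$id[species$name == ""]
  reactions <- data.frame(id = ids[!is_sp], label = label[!is_sp],
                          stringsAsFactors = FALSE)
  reactions$label[reactions$label == ""] <-
    reactions$id[reactions$label == ""]
  edges <- data.frame(
    source = ids[el[, 1]], target = ids[el[, 2]],
    kind = gete(attrs$edgekind, ""), sign = gete(attrs$sign, "activating"),
    stringsAsFactors = FALSE
  )

  net <- signaling_network(species, reactions, edges, check = TRUE)
  soft <- validate_network(net)
  attr(net, "validation") <- soft
  net
}

#' Write a signalling network to GraphML
#'
#' The written file round-trips through [read_graphml()] to a network with
#' identical node ids, edge kinds and signs.
#'
#' @param net a [signaling_network()].
#' @param path output file path.
#' @param attrs attribute-name mapping, see [graphml_attrs()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, attrs = graphml_attrs()) {
  stopifnot(inherits(net, "signaling_network"))
  g <- as_igraph(net)
  ren <- c(nodekind = attrs$nodekind, label = attrs$label,
           state = attrs$state)
  for (from in names(ren)) {
    if (ren[[from]] != from) {
      g <- igraph::set_vertex_attr(g, ren[[from]],
                                   value = igraph::vertex_attr(g, from))
      g <- igraph::delete_vertex_attr(g, from)
    }
  }
  ren_e <- c(edgekind = attrs$edgekind, sign = attrs$sign)
  for (from in names(ren_e)) {
    if (ren_e[[from]] != from) {
      g <- igraph::set_edge_attr(g, ren_e[[from]],
                                 value = igraph::edge_attr(g, from))
      g <- igraph::delete_edge_attr(g, from)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
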