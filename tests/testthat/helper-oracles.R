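# Independent oracles. Everything here is deliberately naive and written
# against the documented semantics only: plain BFS over the raw edge list
# (no igraph) for reachability, and exhaustive distribution propagation for
# the token-flow step. The implementation under test must agree with these.

# --- reachability ----------------------------------------------------------

# boolean reachability matrix over all node ids (species + reactions),
# reach[u, v] == TRUE iff a directed path u -> v exists (u reaches itself)
oracle_reachability <- function(net) {
  ids <- c(net$species$id, net$reactions$id)
  n <- length(ids)
  adj <- lapply(ids, function(u) net$edges$target[net$edges$source == u])
  names(adj) <- ids
  reach <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (u in ids) {
    seen <- u
    frontier <- u
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    reach[u, seen] <- TRUE
  }
  reach
}

# strongly connected component of `seed`: u, v strongly connected iff u
# reaches v and v reaches u
oracle_scc <- function(net, seed) {
  reach <- oracle_reachability(net)
  ids <- rownames(reach)
  ids[reach[seed, ] & reach[, seed]]
}

# core plus all ancestors and descendants of the core
oracle_weak_augment <- function(net, core) {
  reach <- oracle_reachability(net)
  ids <- rownames(reach)
  to_core <- apply(reach[, core, drop = FALSE], 1, any)
  from_core <- apply(reach[core, , drop = FALSE], 2, any)
  ids[to_core | from_core]
}

# --- exact Markov-chain enumeration of the token-flow step -----------------

oracle_permutations <- function(n) {
  if (n == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

oracle_structure <- function(net, threshold = 1L) {
  sp <- net$species$id
  rx <- net$reactions$id
  ed <- net$edges
  list(
    sp = sp, rx = rx, threshold = threshold,
    re = lapply(rx, function(r)
      match(ed$source[ed$kind == "reactant" & ed$target == r], sp)),
    pr = lapply(rx, function(r)
      match(ed$target[ed$kind == "product" & ed$source == r], sp)),
    ma = lapply(rx, function(r)
      match(ed$source[ed$kind == "modifier" & ed$target == r &
                        ed$sign == "activating"], sp)),
    mi = lapply(rx, function(r)
      match(ed$source[ed$kind == "modifier" & ed$target == r &
                        ed$sign == "inhibiting"], sp)),
    sinks = which(!sp %in% ed$source[ed$kind %in% c("reactant", "modifier")])
  )
}

# propagate an exact distribution over token states through one time step:
# average over all reaction orders, all k draws, all sink losses
oracle_step_dist <- function(dist, os) {
  acc <- new.env(parent = emptyenv())
  add <- function(state, p) {
    key <- paste(state, collapse = ",")
    assign(key, p + (if (exists(key, acc)) get(key, acc) else 0), acc)
  }
  sink_branch <- function(state, p, sinks) {
    if (length(sinks) == 0) return(add(state, p))
    s <- sinks[1]
    v <- state[s]
    for (d in 0:v) {
      st <- state
      st[s] <- v - d
      sink_branch(st, p / (v + 1), sinks[-1])
    }
  }
  fire_seq <- function(state, p, order) {
    if (length(order) == 0) return(sink_branch(state, p, os$sinks))
    j <- order[1]
    gated <- (length(os$ma[[j]]) > 0 &&
                any(state[os$ma[[j]]] < os$threshold)) ||
             (length(os$mi[[j]]) > 0 &&
                any(state[os$mi[[j]]] >= os$threshold))
    if (gated || length(os$re[[j]]) == 0) {
      return(fire_seq(state, p, order[-1]))
    }
    m <- min(state[os$re[[j]]])
    for (k in 0:m) {
      st <- state
      if (k > 0) {
        st[os$re[[j]]] <- st[os$re[[j]]] - k
        st[os$pr[[j]]] <- st[os$pr[[j]]] + k
      }
      fire_seq(st, p / (m + 1), order[-1])
    }
  }
  perms <- oracle_permutations(length(os$rx))
  for (key in names(dist)) {
    state <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    p0 <- dist[[key]] / nrow(perms)
    for (r in seq_len(nrow(perms))) {
      fire_seq(state, p0, perms[r, , drop = TRUE])
    }
  }
  out <- sapply(ls(acc), function(k) get(k, acc))
  stopifnot(abs(sum(out) - sum(unlist(dist))) < 1e-9)
  as.list(out)
}

# exact per-species mean trajectory over `steps` time steps from a fixed
# initial state
oracle_exact_means <- function(net, init, steps, threshold = 1L) {
  os <- oracle_structure(net, threshold)
  init <- init[os$sp]
  dist <- stats::setNames(list(1), paste(init, collapse = ","))
  means <- matrix(NA_real_, nrow = steps + 1, ncol = length(os$sp),
                  dimnames = list(paste0("t", 0:steps), os$sp))
  dist_mean <- function(d) {
    m <- numeric(length(os$sp))
    for (key in names(d)) {
      m <- m + as.integer(strsplit(key, ",", fixed = TRUE)[[1]]) * d[[key]]
    }
    m
  }
  means[1, ] <- dist_mean(dist)
  for (t in seq_len(steps)) {
    dist <- oracle_step_dist(dist, os)
    means[t + 1, ] <- dist_mean(dist)
  }
  means
}

# --- shared miniature fixtures --------------------------------------------

# A -> r1 -> B, A -> r2 -> C : two reactions competing for one reactant
fork_network <- function() {
  signaling_network(
    species = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("r1", "r2")),
    edges = data.frame(
      source = c("A", "r1", "A", "r2"),
      target = c("r1", "B", "r2", "C"),
      kind = c("reactant", "product", "reactant", "product"))
  )
}

# A -> r -> {B, C} : one firing feeds two product places
two_product_network <- function() {
  signaling_network(
    species = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = "r"),
    edges = data.frame(
      source = c("A", "r", "r"),
      target = c("r", "B", "C"),
      kind = c("reactant", "product", "product"))
  )
}
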