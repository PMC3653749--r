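#' Simulation configuration
#'
#' Bundles the parameters of a token-flow ensemble. The defaults are the
#' study conditions of the method: 500 stochastic runs over 20 time points,
#' 100 tokens placed on every source species at time zero, and a seed-species
#' token level chosen per scenario (100 control, 10 knockdown, 500
#' overexpression).
#'
#' @param seed_species id of the species whose initial token level the
#'   scenario perturbs.
#' @param seed_tokens tokens placed on `seed_species` at time zero
#'   (overrides its role-based assignment if it is a source).
#' @param n_runs number of independent stochastic runs per ensemble
#'   (at least 2, so the run-to-run variance is defined).
#' @param n_timepoints number of simulated steps; the trajectory has
#'   `n_timepoints + 1` states including time zero.
#' @param source_tokens tokens placed on every source species at time zero.
#' @param rng_seed integer seed; together with the run index it fully
#'   determines every trajectory.
#' @param modifier_threshold token count at which a modifier place switches
#'   its gate: an activating modifier must hold at least this many tokens for
#'   the reaction to fire, an inhibiting modifier blocks it when it does.
#' @return An object of class `spn_config` (a list of the above).
#' @export
spn_config <- function(seed_species, seed_tokens = 100L, n_runs = 500L,
                       n_timepoints = 20L, source_tokens = 100L,
                       rng_seed = 1L, modifier_threshold = 1L) {
  stopifnot(
    is.character(seed_species), length(seed_species) == 1,
    seed_tokens >= 0, source_tokens >= 0,
    n_runs >= 1, n_timepoints >= 0, modifier_threshold >= 1
  )
  structure(
    list(seed_species = seed_species,
         seed_tokens = as.integer(seed_tokens),
         n_runs = as.integer(n_runs),
         n_timepoints = as.integer(n_timepoints),
         source_tokens = as.integer(source_tokens),
         rng_seed = as.integer(rng_seed),
         modifier_threshold = as.integer(modifier_threshold)),
    class = "spn_config"
  )
}

#' Assign flow roles to species
#'
#' A species is a *source* (token entry point, the beginning of a path) iff
#' it has no incoming product edge, and a *sink* (end of a path,
#' self-regulating) iff it has no outgoing reactant or modifier edge. A
#' species that is both is isolated in flow terms.
#'
#' @param net a [signaling_network()].
#' @return A data.frame with columns `id`, `is_source`, `is_sink` and `role`
#'   (`"source"`, `"sink"`, `"internal"` or `"isolated"`).
#' @export
assign_roles <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  sp <- net$species$id
  ed <- net$edges
  has_in <- sp %in% ed$target[ed$kind == "product"]
  has_out <- sp %in% ed$source[ed$kind %in% c("reactant", "modifier")]
  is_source <- !has_in
  is_sink <- !has_out
  role <- ifelse(is_source & is_sink, "isolated",
          ifelse(is_source, "source",
          ifelse(is_sink, "sink", "internal")))
  data.frame(id = sp, is_source = is_source, is_sink = is_sink, role = role,
             stringsAsFactors = FALSE)
}

#' Initial token assignment
#'
#' Sources receive `source_tokens`, the seed species receives `seed_tokens`
#' (overriding its role-based assignment if it is itself a source), all other
#' species start at zero. Sources are seeded at time zero only; they are not
#' replenished during the simulation.
#'
#' @param net a [signaling_network()].
#' @param roles role table from [assign_roles()]; computed if `NULL`.
#' @param config an [spn_config()].
#' @return Named integer vector of token counts, one entry per species.
#' @export
init_tokens <- function(net, config, roles = NULL) {
  stopifnot(inherits(net, "signaling_network"), inherits(config, "spn_config"))
  if (is.null(roles)) roles <- assign_roles(net)
  if (!config$seed_species %in% net$species$id) {
    stop(sprintf("seed species '%s' is not in the network",
                 config$seed_species))
  }
  tokens <- integer(nrow(net$species))
  names(tokens) <- net$species$id
  tokens[roles$id[roles$is_source]] <- config$source_tokens
  tokens[config$seed_species] <- config$seed_tokens
  tokens
}

# Precompute integer-index views of the network for the inner loops.
compile_network <- function(net, roles = NULL, threshold = 1L) {
  sp <- net$species$id
  idx <- seq_along(sp)
  names(idx) <- sp
  if (is.null(roles)) roles <- assign_roles(net)
  ed <- net$edges
  rx <- net$reactions$id
  rx_re <- rx_pr <- rx_ma <- rx_mi <- vector("list", length(rx))
  for (j in seq_along(rx)) {
    r <- rx[j]
    rx_re[[j]] <- unname(idx[ed$source[ed$kind == "reactant" & ed$target == r]])
    rx_pr[[j]] <- unname(idx[ed$target[ed$kind == "product" & ed$source == r]])
    mod_src <- ed$source[ed$kind == "modifier" & ed$target == r]
    mod_sign <- ed$sign[ed$kind == "modifier" & ed$target == r]
    rx_ma[[j]] <- unname(idx[mod_src[mod_sign == "activating"]])
    rx_mi[[j]] <- unname(idx[mod_src[mod_sign == "inhibiting"]])
  }
  list(
    sp_ids = sp, n_sp = length(sp), n_rx = length(rx), rx_ids = rx,
    rx_re = rx_re, rx_pr = rx_pr, rx_ma = rx_ma, rx_mi = rx_mi,
    sinks = unname(idx[roles$id[roles$is_sink]]),
    threshold = as.integer(threshold)
  )
}

# One firing attempt for reaction j against an unnamed integer state vector.
fire_one <- function(state, cn, j) {
  ma <- cn$rx_ma[[j]]
  if (length(ma) && any(state[ma] < cn$threshold)) return(state)
  mi <- cn$rx_mi[[j]]
  if (length(mi) && any(state[mi] >= cn$threshold)) return(state)
  re <- cn$rx_re[[j]]
  if (length(re) == 0L) return(state)  # no reactant place: nothing to move
  m <- min(state[re])
  if (m > 0L) {
    k <- sample.int(m + 1L, 1L) - 1L
    if (k > 0L) {
      state[re] <- state[re] - k
      pr <- cn$rx_pr[[j]]
      state[pr] <- state[pr] + k
    }
  }
  state
}

# One full time step: every reaction fired once in a fresh uniformly-random
# order, then every sink loses d ~ Uniform{0..its current tokens}.
step_tokens <- function(state, cn) {
  if (cn$n_rx > 0L) {
    ord <- if (cn$n_rx == 1L) 1L else sample.int(cn$n_rx)
    for (j in ord) state <- fire_one(state, cn, j)
  }
  for (s in cn$sinks) {
    v <- state[s]
    if (v > 0L) state[s] <- v - (sample.int(v + 1L, 1L) - 1L)
  }
  state
}

#' Fire a single transition
#'
#' Attempts one firing of `reaction` against the given token state. With
#' `m = min` over the reaction's reactant places, a token count
#' `k ~ Uniform{0, ..., m}` is drawn, removed from every reactant place and
#' added to every product place. The firing is vacuous (`k = 0` forced) when
#' `m = 0`, and the reaction is gated shut — no change at all — when any
#' activating modifier place holds fewer than `modifier_threshold` tokens or
#' any inhibiting modifier place holds at least that many. Modifier places
#' are never consumed.
#'
#' Consumes random numbers from R's global RNG stream; wrap in
#' [set.seed()] for reproducibility.
#'
#' @param state named integer vector of tokens per species id.
#' @param reaction a reaction id in `net`.
#' @param net a [signaling_network()].
#' @param modifier_threshold gate threshold, see [spn_config()].
#' @return The updated named token vector.
#' @export
fire_transition <- function(state, reaction, net, modifier_threshold = 1L) {
  stopifnot(inherits(net, "signaling_network"))
  j <- match(reaction, net$reactions$id)
  if (is.na(j)) stop(sprintf("unknown reaction '%s'", reaction))
  cn <- compile_network(net, threshold = modifier_threshold)
  out <- fire_one(unname(state[cn$sp_ids]), cn, j)
  names(out) <- cn$sp_ids
  out
}

#' Advance the token state by one time point
#'
#' Fires every reaction exactly once in a fresh uniformly-random order (the
#' stochastic interleaving of simultaneously enabled transitions), then lets
#' every sink species lose `d ~ Uniform{0, ..., current tokens}` — the
#' self-regulation that prevents token build-up at zero-out-degree nodes.
#'
#' @inheritParams fire_transition
#' @param roles role table from [assign_roles()]; computed if `NULL`.
#' @return The updated named token vector.
#' @export
spn_step <- function(state, net, roles = NULL, modifier_threshold = 1L) {
  stopifnot(inherits(net, "signaling_network"))
  cn <- compile_network(net, roles, threshold = modifier_threshold)
  out <- step_tokens(unname(state[cn$sp_ids]), cn)
  names(out) <- cn$sp_ids
  out
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  code
}

# Reproducible per-run seeds: a single stream seeded with rng_seed yields the
# seed of run i as the i-th draw, so any run is reproducible standalone.
run_seeds <- function(rng_seed, n) {
  with_preserved_rng({
    set.seed(rng_seed)
    sample.int(2147483646L, n)
  })
}

run_trajectory <- function(state0, cn, n_timepoints) {
  traj <- matrix(0L, nrow = n_timepoints + 1L, ncol = cn$n_sp)
  traj[1L, ] <- state0
  state <- state0
  for (t in seq_len(n_timepoints)) {
    state <- step_tokens(state, cn)
    traj[t + 1L, ] <- state
  }
  traj
}

#' Simulate one stochastic run
#'
#' Repeatedly applies [spn_step()] from the initial assignment of
#' [init_tokens()]. The trajectory is fully determined by `config$rng_seed`
#' and the run index: run `run` of [simulate_ensemble()] with the same
#' configuration is bit-identical to `simulate_run(..., run = run)`.
#'
#' @param net a [signaling_network()].
#' @param config an [spn_config()].
#' @param run run index (1-based).
#' @param roles role table from [assign_roles()]; computed if `NULL`.
#' @return Integer matrix with `n_timepoints + 1` rows (times 0..T) and one
#'   column per species.
#' @export
simulate_run <- function(net, config, run = 1L, roles = NULL) {
  stopifnot(inherits(net, "signaling_network"), inherits(config, "spn_config"))
  if (is.null(roles)) roles <- assign_roles(net)
  cn <- compile_network(net, roles, config$modifier_threshold)
  state0 <- unname(init_tokens(net, config, roles)[cn$sp_ids])
  seed_i <- run_seeds(config$rng_seed, run)[run]
  traj <- with_preserved_rng({
    set.seed(seed_i)
    run_trajectory(state0, cn, config$n_timepoints)
  })
  dimnames(traj) <- list(paste0("t", 0:config$n_timepoints), cn$sp_ids)
  traj
}

#' Simulate an ensemble and summarise token trajectories
#'
#' Runs `config$n_runs` independent stochastic runs and records, per species
#' and per time point, the ensemble mean and the unbiased (n - 1) sample
#' variance of the token count. These are the quantities the perturbation
#' screen consumes: the mean proxies the expression level, the variance
#' enters the t statistic denominator.
#'
#' At time zero the mean equals the deterministic initial assignment exactly
#' and the variance is zero.
#'
#' @inheritParams simulate_run
#' @return An object of class `spn_trajectory`: list with `mean` and
#'   `variance` (species x time matrices, columns `t0..tT`), `n_runs`, and
#'   `config`.
#' @export
simulate_ensemble <- function(net, config, roles = NULL) {
  stopifnot(inherits(net, "signaling_network"), inherits(config, "spn_config"))
  if (config$n_runs < 2) stop("n_runs must be at least 2")
  if (is.null(roles)) roles <- assign_roles(net)
  cn <- compile_network(net, roles, config$modifier_threshold)
  state0 <- unname(init_tokens(net, config, roles)[cn$sp_ids])
  nt <- config$n_timepoints
  seeds <- run_seeds(config$rng_seed, config$n_runs)

  s1 <- matrix(0, nrow = cn$n_sp, ncol = nt + 1L)
  s2 <- matrix(0, nrow = cn$n_sp, ncol = nt + 1L)
  with_preserved_rng({
    for (i in seq_len(config$n_runs)) {
      set.seed(seeds[i])
      traj <- run_trajectory(state0, cn, nt)
      s1 <- s1 + t(traj)
      s2 <- s2 + t(traj)^2
    }
  })
  n <- config$n_runs
  mu <- s1 / n
  va <- (s2 - n * mu^2) / (n - 1)
  va[va < 0] <- 0  # guard against tiny negative round-off
  dimnames(mu) <- dimnames(va) <-
    list(cn$sp_ids, paste0("t", 0:nt))
  structure(
    list(mean = mu, variance = va, n_runs = n, config = config),
    class = "spn_trajectory"
  )
}

#' @export
print.spn_trajectory <- function(x, ...) {
  nt <- ncol(x$mean) - 1L
  cat(sprintf(
    "Token-flow ensemble summary: %d species, %d time points, %d runs\n",
    nrow(x$mean), nt, x$n_runs))
  cat(sprintf("  seed species '%s' with %d tokens at t = 0\n",
              x$config$seed_species, x$config$seed_tokens))
  fin <- x$mean[, ncol(x$mean)]
  top <- sort(fin, decreasing = TRUE)
  top <- head(top, 5)
  cat(sprintf("  final-time means (top %d): %s\n", length(top),
              paste(sprintf("%s=%.2f", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Final-time-point summary of an ensemble
#'
#' @param x an `spn_trajectory`.
#' @param ... unused.
#' @return data.frame with `id`, `mean` and `variance` at the last simulated
#'   time point.
#' @export
final_timepoint <- function(x, ...) {
  stopifnot(inherits(x, "spn_trajectory"))
  j <- ncol(x$mean)
  data.frame(id = rownames(x$mean), mean = unname(x$mean[, j]),
             variance = unname(x$variance[, j]), stringsAsFactors = FALSE)
}
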