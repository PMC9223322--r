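#' Discrete diffusion model configuration
#'
#' Parameters of the reentry-detection stage. `tau` is the minimum
#' refractory wavelength in node steps: a unidirectional conduction block
#' induces micro-anatomical reentry iff the blocked site sits on a closed
#' loop of length at least `tau`. With nodes one voxel apart, `tau`
#' approximately equals the physical refractory wavelength divided by the
#' voxel edge (e.g. `tau = 10` is about 3 mm at 300 micrometre resolution).
#'
#' @param tau refractory wavelength in node steps, integer >= 2 (the
#'   automaton/oracle equivalence is exact for `tau >= 3`).
#' @param pacing source of the paced wavefront: `list(type = "face",
#'   axis = 1, side = "min")` paces every node whose home voxel lies on a
#'   boundary layer of the occupied bounding box; `list(type = "nodes",
#'   ids = ...)` paces explicit nodes; `"all"` paces everywhere (making
#'   every component reachable).
#' @param max_steps simulation horizon for [simulate_block()]; default
#'   (`NULL`) is `n_nodes + tau + 2`, enough for any single loop to close.
#' @return An object of class `ddm_config`.
#' @export
ddm_config <- function(tau = 10L, pacing = list(type = "face", axis = 1, side = "min"),
                       max_steps = NULL) {
  tau <- as.integer(tau)
  if (tau < 2L) stop("`tau` must be >= 2")
  if (!is.null(max_steps) && max_steps <= tau)
    stop("`max_steps` must exceed `tau`")
  structure(list(tau = tau, pacing = pacing, max_steps = max_steps),
            class = "ddm_config")
}

# Resolve a pacing specification to node ids (1-based).
pacing_nodes <- function(net, pacing) {
  if (identical(pacing, "all") ||
      (is.list(pacing) && identical(pacing$type, "all")))
    return(net$nodes$id)
  if (is.list(pacing) && identical(pacing$type, "nodes"))
    return(as.integer(pacing$ids))
  if (is.list(pacing) && identical(pacing$type, "face")) {
    ax <- pacing$axis %||% 1
    v <- net$nodes[[c("vi", "vj", "vk")[ax]]]
    lvl <- if (identical(pacing$side %||% "min", "min")) min(v) else max(v)
    return(net$nodes$id[v == lvl])
  }
  stop("unrecognised pacing specification")
}

net_edge_arrays <- function(net) {
  list(n = nrow(net$nodes),
       eu = as.integer(net$edges$from - 1L),
       ev = as.integer(net$edges$to - 1L))
}

find_pair_index <- function(net, node, blocked_neighbour) {
  # pair p = 2*(e-1) + d, d = 0 when the blocked transmission runs from
  # edges$from -> edges$to
  e1 <- which(net$edges$from == blocked_neighbour & net$edges$to == node)
  if (length(e1)) return(2L * (e1[1] - 1L))
  e2 <- which(net$edges$from == node & net$edges$to == blocked_neighbour)
  if (length(e2)) return(2L * (e2[1] - 1L) + 1L)
  stop("`node` and `blocked_neighbour` are not adjacent in the network")
}

#' Shortest return length past a unidirectional block
#'
#' The graph-theoretic oracle for reentry: the length (edge count) of the
#' shortest path from `blocked_neighbour` back to `node` that does not use
#' the blocked edge, plus one for the blocked edge itself — i.e. the length
#' of the shortest closed loop through the blocked site. `Inf` if no
#' alternative path exists (the edge is a bridge).
#'
#' @param net a `spatial_network`.
#' @param node,blocked_neighbour adjacent node ids; transmission
#'   `blocked_neighbour -> node` is blocked.
#' @return Integer loop length, or `Inf`.
#' @examples
#' # on an n-cycle the only return path is the rest of the ring: length n
#' @export
shortest_return_length <- function(net, node, blocked_neighbour) {
  a <- net_edge_arrays(net)
  p <- find_pair_index(net, node, blocked_neighbour)
  path <- ddm_return_paths_cpp(a$n, a$eu, a$ev, p)[[1]]
  if (length(path) == 0L) Inf else length(path)
}

#' Simulate one unidirectional conduction block
#'
#' Runs the discrete diffusion model (DDM) for a single block: a paced
#' wavefront must reach the block site (phase 1); the re-initiation dynamics
#' are then simulated on recovered tissue as a synchronous
#' excitation/refractory automaton started at `blocked_neighbour`, with
#' transmission `blocked_neighbour -> node` suppressed on its first arrival
#' only (phase 2). Reentry occurs iff the wave re-enters the blocked site
#' through the alternative path after its refractory period — equivalently
#' (for `tau >= 3`), iff the shortest return loop has length `>= tau`.
#'
#' @inheritParams shortest_return_length
#' @param cfg a [ddm_config()].
#' @return List with elements `reentry` (flag), `loop` (node-id sequence of
#'   the reentrant loop, or `NULL`), `reachable` (did the paced wave reach
#'   the block site) and `arrival` (paced arrival time).
#' @export
simulate_block <- function(net, node, blocked_neighbour, cfg = ddm_config()) {
  a <- net_edge_arrays(net)
  p <- find_pair_index(net, node, blocked_neighbour)
  pace <- as.integer(pacing_nodes(net, cfg$pacing) - 1L)
  ms <- cfg$max_steps %||% (a$n + cfg$tau + 2L)
  res <- ddm_simulate_pair_cpp(a$n, a$eu, a$ev, p, cfg$tau, as.integer(ms), pace)
  if (!res$reachable)
    warning("pacing source does not reach the block site; reentry trivially FALSE")
  list(reentry = isTRUE(res$reentry),
       loop = if (length(res$loop)) as.integer(res$loop) else NULL,
       reachable = isTRUE(res$reachable),
       arrival = res$arrival)
}

#' Identify the micro-reentrant substrate of a network
#'
#' Evaluates a unidirectional block at every (node, incoming-direction) pair
#' whose block site the paced wavefront reaches, under uniform block
#' susceptibility, and collects the pairs whose block induces reentry. Two
#' engines are provided and agree exactly: `"oracle"` applies the defining
#' graph criterion (finite shortest return loop `>= tau`) with a bridge
#' pre-pass and truncated breadth-first searches — fast enough for ensemble
#' sweeps; `"ddm"` runs the excitation automaton of [simulate_block()] for
#' every pair.
#'
#' @param net a `spatial_network`.
#' @param cfg a [ddm_config()].
#' @param engine `"oracle"` or `"ddm"`.
#' @param collect which reentrant circuits to extract as explicit loops:
#'   `"auto"` (all, unless there are more than `max_circuits`), `"all"`, or
#'   `"none"` (flags only; per-voxel counts unavailable).
#' @param max_circuits cap used by `collect = "auto"`.
#' @return An object of class `substrate_result`: tibble `pairs` (one row
#'   per evaluated directed pair with `node`, `blocked_neighbour`,
#'   `reentry`), `substrate_nodes`, `circuits` (list of node-id loops),
#'   `circuit_pairs`, `per_voxel_counts` (3-d array of the number of
#'   extracted circuits intersecting each voxel, or `NULL`),
#'   `n_substrates`, `n_evaluated`, `tau`.
#' @export
find_substrate <- function(net, cfg = ddm_config(),
                           engine = c("oracle", "ddm"),
                           collect = c("auto", "all", "none"),
                           max_circuits = 5000L) {
  engine <- match.arg(engine)
  collect <- match.arg(collect)
  a <- net_edge_arrays(net)
  m <- length(a$eu)
  if (m == 0L || a$n == 0L) stop("network has no edges to evaluate")
  pace <- as.integer(pacing_nodes(net, cfg$pacing) - 1L)

  if (engine == "oracle") {
    status <- ddm_oracle_scan_cpp(a$n, a$eu, a$ev, cfg$tau, pace)
  } else {
    ms <- cfg$max_steps %||% (a$n + cfg$tau + 2L)
    status <- integer(2L * m)
    for (p in seq_len(2L * m) - 1L) {
      res <- ddm_simulate_pair_cpp(a$n, a$eu, a$ev, p, cfg$tau,
                                   as.integer(ms), pace)
      status[p + 1L] <- if (!res$reachable) -1L else as.integer(res$reentry)
    }
  }

  pair_id <- seq_len(2L * m) - 1L
  e <- pair_id %/% 2L
  d <- pair_id %% 2L
  b <- ifelse(d == 0L, a$eu[e + 1L], a$ev[e + 1L]) + 1L
  aa <- ifelse(d == 0L, a$ev[e + 1L], a$eu[e + 1L]) + 1L
  evaluated <- status >= 0L
  pairs <- tibble(pair = pair_id, node = aa, blocked_neighbour = b,
                  evaluated = evaluated, reentry = status == 1L)

  reentry_pairs <- pair_id[status == 1L]
  circuits <- NULL
  counts <- NULL
  if (collect == "all" ||
      (collect == "auto" && length(reentry_pairs) <= max_circuits)) {
    circuits <- extract_circuits(net, reentry_pairs)
    counts <- circuit_voxel_counts(net, circuits)
  }
  structure(list(
    pairs = pairs,
    substrate_nodes = sort(unique(aa[status == 1L])),
    circuits = circuits,
    circuit_pairs = reentry_pairs,
    per_voxel_counts = counts,
    n_substrates = sum(status == 1L),
    n_evaluated = sum(evaluated),
    tau = cfg$tau,
    dims = net$dims,
    engine = engine
  ), class = "substrate_result")
}

# Closed loops (node-id sequences, blocked edge implicit) for directed pairs.
extract_circuits <- function(net, pair_ids) {
  if (length(pair_ids) == 0L) return(list())
  a <- net_edge_arrays(net)
  paths <- ddm_return_paths_cpp(a$n, a$eu, a$ev, as.integer(pair_ids))
  lapply(paths, as.integer)
}

# Number of extracted circuits intersecting each voxel (each circuit counts
# once per voxel it passes through). `weights` gives sampling multiplicity.
circuit_voxel_counts <- function(net, circuits, weights = NULL, dims = NULL) {
  dims <- dims %||% net$dims
  if (is.null(dims)) stop("network carries no grid dimensions")
  counts <- array(0, dims)
  if (length(circuits) == 0L) return(counts)
  weights <- weights %||% rep(1, length(circuits))
  for (ci in seq_along(circuits)) {
    ids <- circuits[[ci]]
    vox <- cbind(net$nodes$vi[ids], net$nodes$vj[ids], net$nodes$vk[ids])
    li <- unique(linear_index(vox, dims))
    counts[li] <- counts[li] + weights[ci]
  }
  counts
}

#' @export
print.substrate_result <- function(x, ...) {
  cat(sprintf("<substrate_result> %d reentry-inducing blocks of %d evaluated (tau = %d), %d substrate nodes\n",
              x$n_substrates, x$n_evaluated, x$tau, length(x$substrate_nodes)))
  invisible(x)
}
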