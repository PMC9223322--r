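#' Coupling configuration
#'
#' Parameters of the distance-dependent transverse attachment probability
#' \deqn{p(x; r, c) = 1 / (e^{r(x - c)} + 1),}
#' the logistic law used to couple nodes on different fibres. `c` is the
#' characteristic coupling distance (voxel units) and plays the role of an
#' (inverse) interstitial fibrosis grade: large `c` means well-coupled
#' tissue, `c -> 0` means fibres insulated from their neighbours. Only node
#' pairs closer than `cutoff` are considered for connection.
#'
#' @param c characteristic distance (voxel units), >= 0.
#' @param r steepness (dimensionless), > 0.
#' @param cutoff candidate-pair distance bound (voxel units), > 0.
#' @param seed RNG seed for the edge draw.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(c = 0.5, r = 7, cutoff = 2, seed = 1L) {
  if (r <= 0) stop("`r` must be > 0")
  if (c < 0) stop("`c` must be >= 0")
  if (cutoff <= 0) stop("`cutoff` must be > 0")
  structure(list(c = c, r = r, cutoff = cutoff, seed = as.integer(seed)),
            class = "coupling_config")
}

#' Transverse connection probability
#'
#' The logistic attachment law \eqn{p(x; r, c) = 1/(e^{r(x-c)} + 1)}:
#' strictly decreasing in the node separation `x`, equal to 1/2 at `x = c`.
#'
#' @param x node separation(s), voxel units, >= 0.
#' @param r steepness.
#' @param c characteristic distance.
#' @return Probabilities in (0, 1), vectorised over `x`.
#' @examples
#' connection_probability(1, r = 7, c = 1) # 0.5 at the midpoint
#' @export
connection_probability <- function(x, r = 7, c = 0.5) {
  if (any(x < 0)) stop("`x` must be >= 0")
  1 / (exp(r * (x - c)) + 1)
}

#' Candidate node pairs within a cutoff distance
#'
#' Exactly the unordered pairs of nodes separated by less than `cutoff`,
#' found with a uniform-cell spatial index but contractually identical to
#' brute-force all-pairs enumeration. Rows are sorted by `(i, j)` with
#' `i < j`, so the output order is a deterministic function of the node set.
#'
#' @param nodes tibble/data frame with columns `x`, `y`, `z` (and optionally
#'   `id`; row order defines ids otherwise).
#' @param cutoff distance bound (voxel units).
#' @return Tibble with columns `i`, `j` (node row indices, `i < j`) and
#'   `dist`.
#' @export
candidate_pairs <- function(nodes, cutoff = 2) {
  if (nrow(nodes) < 2L)
    return(tibble(i = integer(), j = integer(), dist = numeric()))
  px <- nodes$x; py <- nodes$y; pz <- nodes$z
  cs <- cutoff
  cx <- floor(px / cs); cy <- floor(py / cs); cz <- floor(pz / cs)
  key <- paste(cx, cy, cz)
  cells <- split(seq_along(px), key)
  cell_of <- function(kx, ky, kz) paste(kx, ky, kz)
  # 13 half-space neighbour offsets + the self cell: each unordered cell pair
  # (and pair within a cell) is visited exactly once
  offs <- list(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
               c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1),
               c(1,-1,1), c(1,-1,-1))
  res_i <- list(); res_j <- list(); nres <- 0L
  add_pairs <- function(a, b) {
    # cross pairs between node index vectors a and b
    nres <<- nres + 1L
    res_i[[nres]] <<- rep(a, each = length(b))
    res_j[[nres]] <<- rep(b, times = length(a))
  }
  keys <- names(cells)
  key_coords <- do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
  for (ci in seq_along(cells)) {
    a <- cells[[ci]]
    if (length(a) > 1L) { # within-cell pairs
      cmb <- which(upper.tri(matrix(0, length(a), length(a))), arr.ind = TRUE)
      nres <- nres + 1L
      res_i[[nres]] <- a[cmb[, 1]]
      res_j[[nres]] <- a[cmb[, 2]]
    }
    kc <- key_coords[ci, ]
    for (off in offs) {
      nb <- cells[[cell_of(kc[1] + off[1], kc[2] + off[2], kc[3] + off[3])]]
      if (!is.null(nb)) add_pairs(a, nb)
    }
  }
  if (nres == 0L) return(tibble(i = integer(), j = integer(), dist = numeric()))
  ii <- unlist(res_i, use.names = FALSE)
  jj <- unlist(res_j, use.names = FALSE)
  dd <- sqrt((px[ii] - px[jj])^2 + (py[ii] - py[jj])^2 + (pz[ii] - pz[jj])^2)
  keep <- dd < cutoff
  ii <- ii[keep]; jj <- jj[keep]; dd <- dd[keep]
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  o <- order(ii, jj)
  tibble(i = ii[o], j = jj[o], dist = dd[o])
}

# Internal: skeleton = everything about a network that does not depend on
# the coupling draw (node table, longitudinal edges, candidate transverse
# pairs). Sweeping c re-uses the skeleton and redraws only edge uniforms.
network_skeleton <- function(tracts, cutoff = 2, connect_same_tract = FALSE) {
  stopifnot(inherits(tracts, "tract_set"))
  nodes <- tracts$nodes
  if (nrow(nodes) == 0L) stop("tract set has no node points")
  # longitudinal edges: consecutive nodes of the same tract, p = 1
  lon <- nodes |>
    dplyr::arrange(.data$tract, .data$along) |>
    dplyr::group_by(.data$tract) |>
    dplyr::mutate(nxt = dplyr::lead(.data$id)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$nxt))
  lon_edges <- tibble(from = lon$id, to = lon$nxt)
  cand <- candidate_pairs(nodes, cutoff)
  same_tract <- nodes$tract[cand$i] == nodes$tract[cand$j]
  if (!connect_same_tract) cand <- cand[!same_tract, ]
  list(nodes = nodes, lon_edges = lon_edges, cand = cand)
}

realise_edges <- function(skel, c, r, seed) {
  p <- connection_probability(skel$cand$dist, r = r, c = c)
  u <- withr::with_seed(seed, runif(nrow(skel$cand)))
  keep <- u < p
  tibble(from = skel$cand$i[keep], to = skel$cand$j[keep],
         dist = skel$cand$dist[keep])
}

new_spatial_network <- function(nodes, edges, model, config, extra = list()) {
  structure(c(list(nodes = nodes, edges = edges, model = model,
                   config = config), extra),
            class = "spatial_network")
}

#' Build the fibre spatial network
#'
#' Nodes are the tract node points. Consecutive nodes of the same tract are
#' connected deterministically (longitudinal edges, probability 1). Every
#' candidate pair of nodes on *different* tracts closer than `cfg$cutoff`
#' gains a transverse edge independently with probability
#' [connection_probability()] of their separation. Non-adjacent pairs on the
#' same tract get no edge by default (`connect_same_tract = TRUE` to allow
#' them to compete for transverse edges too).
#'
#' One uniform variate is drawn per candidate pair in a fixed pair order, so
#' for a fixed `seed` the edge sets at two couplings `c1 < c2` are nested:
#' every edge present at `c1` is present at `c2`.
#'
#' @param tracts a [generate_tract_set()] result.
#' @param cfg a [coupling_config()].
#' @param connect_same_tract also allow transverse edges between non-adjacent
#'   nodes of one tract.
#' @return An object of class `spatial_network` with tibbles `nodes`
#'   (id, position, home voxel, tract) and `edges` (from, to, type).
#' @export
build_fibre_network <- function(tracts, cfg = coupling_config(),
                                connect_same_tract = FALSE) {
  skel <- network_skeleton(tracts, cfg$cutoff, connect_same_tract)
  tr <- realise_edges(skel, cfg$c, cfg$r, cfg$seed)
  edges <- dplyr::bind_rows(
    tibble(from = skel$lon_edges$from, to = skel$lon_edges$to,
           type = "longitudinal"),
    tibble(from = tr$from, to = tr$to, type = "transverse")
  )
  new_spatial_network(skel$nodes, edges, "fibre", cfg,
                      extra = list(dims = tracts$dims))
}

#' Build the fibre-less null network
#'
#' The comparison model without fibre structure: nodes are placed uniformly
#' at random at about one per occupied voxel, accepting a node only if it is
#' at least `d_sep` from all accepted nodes, and *all* candidate pairs closer
#' than the cutoff are connected with probability
#' [connection_probability()]. No longitudinal edges exist; comparable edge
#' densities therefore require larger `c` than in the fibre model.
#'
#' @param geom a [voxel_geometry()] (non-empty mask).
#' @param cfg a [coupling_config()].
#' @param d_sep minimum node separation (voxel units).
#' @param density target nodes per occupied voxel.
#' @return A `spatial_network` with `model = "null"`; all edges transverse.
#' @export
build_null_network <- function(geom, cfg = coupling_config(), d_sep = 0.7,
                               density = 1) {
  seeds <- derive_seeds(cfg$seed, 2)
  pts <- withr::with_seed(seeds[1],
    sample_seed_points(geom, d_sep, n = ceiling(density * n_occupied(geom))))
  vox <- position_to_voxel(pts)
  nodes <- tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                  vi = vox[, 1], vj = vox[, 2], vk = vox[, 3],
                  tract = NA_integer_, along = NA_integer_,
                  id = seq_len(nrow(pts)))
  skel <- list(nodes = nodes, cand = candidate_pairs(nodes, cfg$cutoff))
  tr <- realise_edges(skel, cfg$c, cfg$r, seeds[2])
  edges <- tibble(from = tr$from, to = tr$to, type = "transverse")
  new_spatial_network(nodes, edges, "null", cfg,
                      extra = list(dims = geom$dim))
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("<spatial_network:%s> %d nodes, %d edges (%d longitudinal, %d transverse), c = %g\n",
              x$model, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "longitudinal"),
              sum(x$edges$type == "transverse"), x$config$c))
  invisible(x)
}

#' Export a network as plain-text edge list and node table
#'
#' Writes `<stem>_nodes.csv` and `<stem>_edges.csv`, a documented interchange
#' form that round-trips through [read_network_csv()].
#' @param net a `spatial_network`.
#' @param stem output path stem.
#' @return Invisibly, the files written.
#' @export
write_network_csv <- function(net, stem) {
  fn <- paste0(stem, "_nodes.csv"); fe <- paste0(stem, "_edges.csv")
  utils::write.csv(net$nodes, fn, row.names = FALSE)
  utils::write.csv(net$edges, fe, row.names = FALSE)
  invisible(c(fn, fe))
}

#' Read a network written by [write_network_csv()]
#' @param stem path stem used when writing.
#' @param model network model label (`"fibre"` or `"null"`).
#' @return A `spatial_network`.
#' @export
read_network_csv <- function(stem, model = "fibre") {
  nodes <- tibble::as_tibble(utils::read.csv(paste0(stem, "_nodes.csv")))
  edges <- tibble::as_tibble(utils::read.csv(paste0(stem, "_edges.csv")))
  new_spatial_network(nodes, edges, model, NULL)
}
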