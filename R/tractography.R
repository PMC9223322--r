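#' Tractography parameters
#'
#' Controls the modified evenly spaced streamlines (ESS) tracer. Distances
#' are voxel units. Defaults follow standard streamline practice for
#' voxel-resolution fibre data: seeds and streamlines are kept at least
#' `d_sep = 0.7` apart, nodes are placed every 1 voxel length along fibres,
#' and tracts cover the tissue at a target density of 1 node per occupied
#' voxel. The tracer is "longest first": each round traces a pool of
#' candidates and accepts them in decreasing length order, which maximises
#' fibre length while keeping the streamline density approximately uniform.
#'
#' @param d_sep minimum seed/streamline separation (voxel units).
#' @param step integration step (voxel units), in (0, 1].
#' @param max_angle per-step turning limit (radians).
#' @param target_density nodes per occupied voxel.
#' @param node_spacing along-fibre node interval (voxel units).
#' @param max_len maximum points per tract half (length cap).
#' @param round_size candidate tracts traced per acceptance round.
#' @param max_rejections consecutive failed seed draws before a round is
#'   declared exhausted.
#' @param seed RNG seed for seeding and node phases.
#' @return An object of class `tractography_params`.
#' @export
tractography_params <- function(d_sep = 0.7, step = 0.5, max_angle = pi / 3,
                                target_density = 1, node_spacing = 1,
                                max_len = 2000L, round_size = 64L,
                                max_rejections = 600L, seed = 1L) {
  if (d_sep <= 0) stop("`d_sep` must be > 0")
  if (step <= 0 || step > 1) stop("`step` must be in (0, 1]")
  if (target_density <= 0) stop("`target_density` must be > 0")
  if (node_spacing <= 0) stop("`node_spacing` must be > 0")
  structure(list(d_sep = d_sep, step = step, max_angle = max_angle,
                 target_density = target_density, node_spacing = node_spacing,
                 max_len = as.integer(max_len), round_size = as.integer(round_size),
                 max_rejections = as.integer(max_rejections),
                 seed = as.integer(seed)),
            class = "tractography_params")
}

## ---- grid spatial index (uniform cells, radius queries) ----

new_point_index <- function(cell) {
  e <- new.env(parent = emptyenv())
  list(h = e, cell = cell)
}

pt_key <- function(p, cell) {
  k <- floor(p / cell) + 4L
  as.character(k[1] + 4096 * (k[2] + 4096 * k[3]))
}

index_add <- function(index, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  for (r in seq_len(nrow(pts))) {
    key <- pt_key(pts[r, ], index$cell)
    cur <- index$h[[key]]
    index$h[[key]] <- if (is.null(cur)) pts[r, , drop = FALSE] else rbind(cur, pts[r, ])
  }
  invisible(index)
}

# TRUE if any indexed point lies within `rad` of p.
index_near <- function(index, p, rad) {
  k0 <- floor(p / index$cell) + 4L
  r2 <- rad * rad
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    key <- as.character((k0[1] + dx) + 4096 * ((k0[2] + dy) + 4096 * (k0[3] + dz)))
    m <- index$h[[key]]
    if (!is.null(m)) {
      d2 <- (m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2
      if (any(d2 < r2)) return(TRUE)
    }
  }
  FALSE
}

## ---- seed sampling ----

#' Sample seed points with a minimum separation
#'
#' Dart-throwing sampling of points inside occupied voxels: a candidate is a
#' uniform position inside a uniformly chosen occupied voxel, accepted only
#' if it lies at least `d_sep` from every previously accepted point.
#' Sampling stops when `n` points are placed or after `max_rejections`
#' consecutive failures (the admissible space is then considered exhausted).
#'
#' @param geom a [voxel_geometry()] with at least one occupied voxel.
#' @param d_sep minimum pairwise separation (voxel units).
#' @param n target number of points (default: one per occupied voxel;
#'   `Inf` = fill to exhaustion).
#' @param max_rejections consecutive rejections before stopping.
#' @param index optional existing point index that candidates must also keep
#'   `d_sep` from (used internally for streamline seeding).
#' @param voxels optional integer matrix (m x 3) restricting candidate
#'   positions to these voxels (default: all occupied voxels).
#' @return Numeric matrix (m x 3) of positions in voxel units.
#' @export
sample_seed_points <- function(geom, d_sep = 0.7, n = NULL,
                               max_rejections = 2000L, index = NULL,
                               voxels = NULL) {
  occ <- voxels %||% occupied_voxels(geom)
  if (nrow(occ) == 0L) stop("empty mask: no occupied voxels to seed")
  n <- n %||% nrow(occ)
  own <- new_point_index(d_sep)
  cap <- if (is.finite(n)) as.integer(n) else max(64L, 2L * nrow(occ))
  out <- matrix(NA_real_, cap, 3)
  np <- 0L
  rej <- 0L
  while (np < n && rej < max_rejections) {
    vi <- sample.int(nrow(occ), 1L)
    p <- as.numeric(occ[vi, ]) - 1 + runif(3)
    ok <- !index_near(own, p, d_sep) &&
      (is.null(index) || !index_near(index, p, d_sep))
    if (ok) {
      np <- np + 1L
      if (np > nrow(out)) out <- rbind(out, matrix(NA_real_, nrow(out), 3))
      out[np, ] <- p
      index_add(own, p)
      rej <- 0L
    } else rej <- rej + 1L
  }
  out[seq_len(np), , drop = FALSE]
}

## ---- streamline integration ----

inside_mask <- function(p, geom) {
  v <- floor(p) + 1
  if (v[1] < 1 || v[2] < 1 || v[3] < 1 ||
      v[1] > geom$dim[1] || v[2] > geom$dim[2] || v[3] > geom$dim[3]) return(FALSE)
  geom$mask[v[1], v[2], v[3]]
}

#' Trace a single fibre tract
#'
#' Integrates the orientation field bidirectionally from a seed with fixed
#' step and nearest-voxel orientation lookup. The axial field is followed
#' with sign continuity: at each step the sign of the local vector is chosen
#' to minimise the angle to the previous direction. A tract half terminates
#' when it (i) leaves the mask or reaches a voxel with missing orientation,
#' (ii) would turn by more than `max_angle` in one step, (iii) comes within
#' `d_sep` of a previously accepted tract, or (iv) reaches the length cap.
#'
#' @param seed length-3 position inside the mask (voxel units).
#' @param field an [orientation_field()].
#' @param geom the matching [voxel_geometry()].
#' @param params a [tractography_params()].
#' @param index optional point index of previously accepted tracts
#'   (termination rule iii); `NULL` disables the proximity rule.
#' @return An object of class `fibre_tract`: list with `points` (m x 3
#'   matrix, ordered along the tract) and `seed`.
#' @export
trace_tract <- function(seed, field, geom, params = tractography_params(),
                        index = NULL) {
  validate_geometry_pair(geom, field)
  if (!inside_mask(seed, geom)) stop("seed lies outside the mask")
  v0 <- field_vectors_at(field, position_to_voxel(seed))[1, ]
  if (anyNA(v0)) stop("missing orientation at the seed voxel")
  cos_max <- cos(params$max_angle)

  half <- function(dir0) {
    pts <- matrix(NA_real_, params$max_len, 3)
    np <- 0L
    p <- seed
    dir <- dir0
    repeat {
      vv <- field_vectors_at(field, position_to_voxel(p))[1, ]
      if (anyNA(vv)) break
      if (sum(vv * dir) < 0) vv <- -vv # axial sign continuity
      if (sum(vv * dir) < cos_max) break # (ii) curvature cap
      p2 <- p + params$step * vv
      if (!inside_mask(p2, geom)) break # (i) mask exit
      if (!is.null(index) && index_near(index, p2, params$d_sep)) break # (iii)
      np <- np + 1L
      pts[np, ] <- p2
      if (np >= params$max_len) break # (iv)
      p <- p2
      dir <- vv
    }
    pts[seq_len(np), , drop = FALSE]
  }

  fwd <- half(v0)
  bwd <- half(-v0)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed, 1), fwd)
  structure(list(points = pts, seed = seed), class = "fibre_tract")
}

# Place nodes along a polyline at even arc-length intervals from `phase`.
place_nodes_along <- function(points, node_spacing, phase) {
  if (nrow(points) < 2L) return(matrix(numeric(0), 0, 3))
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  if (total < phase) return(matrix(numeric(0), 0, 3))
  s <- seq(phase, total, by = node_spacing)
  if (length(s) == 0L) return(matrix(numeric(0), 0, 3))
  ix <- findInterval(s, cs, rightmost.closed = TRUE)
  ix[ix >= nrow(points)] <- nrow(points) - 1L
  t_ <- (s - cs[ix]) / pmax(seg[ix], 1e-12)
  points[ix, , drop = FALSE] +
    (points[ix + 1L, , drop = FALSE] - points[ix, , drop = FALSE]) * t_
}

#' Generate a full tract set
#'
#' Runs the modified ESS procedure: rounds of candidate tracts are traced
#' from admissible seeds (at least `d_sep` from all accepted streamline
#' points), then accepted in decreasing length order, re-tracing each
#' candidate against the updated accepted set so the spacing rule holds
#' exactly. Accepted tracts receive node points every `node_spacing` voxel
#' lengths starting at a random phase. Rounds repeat until the node count
#' reaches `target_density` x occupied voxels or no admissible seeds remain.
#'
#' @param geom a [voxel_geometry()].
#' @param field an [orientation_field()] defined on the mask.
#' @param params a [tractography_params()].
#' @return An object of class `tract_set`: list with `tracts` (list of
#'   `fibre_tract`, each with `nodes`, `round`, `order_key`), `nodes` (tibble
#'   of all node points with home voxel and tract id), `params`,
#'   `n_occupied`.
#' @examples
#' fx <- make_fixture(fixture_spec("slab", dims = c(20, 10, 2), thickness = 2))
#' ts <- generate_tract_set(fx$geometry, fx$field,
#'                          tractography_params(seed = 7))
#' nrow(ts$nodes) / n_occupied(fx$geometry) # ~1
#' @export
generate_tract_set <- function(geom, field, params = tractography_params()) {
  validate_geometry_pair(geom, field)
  withr::with_seed(params$seed, generate_tract_set_impl(geom, field, params))
}

generate_tract_set_impl <- function(geom, field, params) {
  n_occ <- n_occupied(geom)
  target_nodes <- params$target_density * n_occ
  accepted <- new_point_index(params$d_sep)
  tracts <- list()
  nodes_list <- list()
  node_count <- 0L
  round_id <- 0L
  occ_all <- occupied_voxels(geom)
  # per-voxel node tally: seeds are drawn only from voxels still below the
  # target density, keeping coverage approximately uniform across regions
  vox_nodes <- array(0, geom$dim)

  repeat {
    if (node_count >= target_nodes) break
    round_id <- round_id + 1L
    open <- occ_all[vox_nodes[linear_index(occ_all, geom$dim)] <
                      params$target_density, , drop = FALSE]
    if (nrow(open) == 0L) break
    seeds <- sample_seed_points(geom, params$d_sep, n = params$round_size,
                                max_rejections = params$max_rejections,
                                index = accepted, voxels = open)
    if (nrow(seeds) == 0L) break
    # provisional traces against the current accepted set, for ordering only
    prov_len <- vapply(seq_len(nrow(seeds)), function(r) {
      tr <- trace_tract(seeds[r, ], field, geom, params, index = accepted)
      nrow(tr$points)
    }, numeric(1))
    ord <- order(prov_len, decreasing = TRUE)
    for (r in ord) {
      if (node_count >= target_nodes) break
      sp <- seeds[r, ]
      if (index_near(accepted, sp, params$d_sep)) next # no longer admissible
      tr <- trace_tract(sp, field, geom, params, index = accepted)
      if (nrow(tr$points) < 2L) next
      index_add(accepted, tr$points)
      phase <- runif(1, 0, params$node_spacing)
      nd <- place_nodes_along(tr$points, params$node_spacing, phase)
      tr$nodes <- nd
      tr$round <- round_id
      tr$order_key <- prov_len[r]
      tracts[[length(tracts) + 1L]] <- tr
      if (nrow(nd) > 0L) {
        vox <- position_to_voxel(nd)
        nodes_list[[length(nodes_list) + 1L]] <-
          tibble(x = nd[, 1], y = nd[, 2], z = nd[, 3],
                 vi = vox[, 1], vj = vox[, 2], vk = vox[, 3],
                 tract = length(tracts), along = seq_len(nrow(nd)))
        node_count <- node_count + nrow(nd)
        vli <- linear_index(vox, geom$dim)
        for (q in vli) vox_nodes[q] <- vox_nodes[q] + 1
      }
    }
  }

  nodes <- if (length(nodes_list)) dplyr::bind_rows(nodes_list) else
    tibble(x = numeric(), y = numeric(), z = numeric(),
           vi = integer(), vj = integer(), vk = integer(),
           tract = integer(), along = integer())
  nodes$id <- seq_len(nrow(nodes))
  structure(list(tracts = tracts, nodes = nodes, params = params,
                 n_occupied = n_occ, dims = geom$dim),
            class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d tracts, %d nodes over %d occupied voxels (%.2f/voxel)\n",
              length(x$tracts), nrow(x$nodes), x$n_occupied,
              nrow(x$nodes) / x$n_occupied))
  invisible(x)
}

#' @export
as_tibble.tract_set <- function(x, ...) x$nodes
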