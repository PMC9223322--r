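# Toy spatial networks built directly from edge lists, for substrate and
# risk tests. Node positions are laid out on a line unless given.

manual_network <- function(edges, n = max(edges), pos = NULL, dims = NULL,
                           types = NULL, model = "null", tracts = NULL) {
  if (is.null(pos)) pos <- cbind(seq_len(n) - 0.5, 0.5, 0.5)
  vox <- floor(pos) + 1
  if (is.null(dims)) dims <- pmax(apply(vox, 2, max), 1)
  nodes <- tibble::tibble(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vi = as.integer(vox[, 1]), vj = as.integer(vox[, 2]),
    vk = as.integer(vox[, 3]),
    tract = if (is.null(tracts)) NA_integer_ else as.integer(tracts),
    along = NA_integer_, id = seq_len(n))
  ed <- tibble::tibble(from = as.integer(edges[, 1]),
                       to = as.integer(edges[, 2]),
                       type = types %||% rep("transverse", nrow(edges)))
  fibrenet:::new_spatial_network(nodes, ed, model, NULL,
                                 extra = list(dims = as.integer(dims)))
}

ring_network <- function(n) {
  e <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  manual_network(t(apply(e, 1, sort)), n = n)
}

chain_network <- function(n) {
  manual_network(cbind(seq_len(n - 1), 2:n), n = n)
}

random_tree_edges <- function(n) {
  par <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L))
  cbind(par[-1], 2:n)
}

# Mixed random test networks: sparse random graphs, trees with chords,
# chorded cycles. Positions uniform in a 20-voxel box.
random_small_network <- function(seed) {
  set.seed(seed)
  n <- sample(6:60, 1)
  style <- sample(1:3, 1)
  if (style == 1) {
    m <- sample(n:(2 * n), 1)
    e <- unique(t(apply(cbind(sample(n, m, TRUE), sample(n, m, TRUE)), 1, sort)))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    if (nrow(e) == 0L) e <- cbind(1L, 2L)
  } else if (style == 2) {
    e <- random_tree_edges(n)
    nc <- sample(0:3, 1)
    if (nc > 0) {
      ch <- unique(t(apply(cbind(sample(n, nc, TRUE), sample(n, nc, TRUE)), 1, sort)))
      ch <- ch[ch[, 1] != ch[, 2], , drop = FALSE]
      e <- unique(rbind(e, ch))
    }
  } else {
    e <- t(apply(cbind(seq_len(n), c(2:n, 1)), 1, sort))
  }
  pos <- matrix(runif(3 * n, 0, 20), n, 3)
  manual_network(e, n = n, pos = pos, dims = c(21, 21, 21))
}

# A small uniform slab with its tract set, shared by several test files.
small_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_fixture(fixture_spec("slab", dims = c(20, 12, 3), thickness = 3))
      ts <- generate_tract_set(fx$geometry, fx$field,
                               tractography_params(seed = 42))
      cache <<- list(fx = fx, ts = ts)
    }
    cache
  }
})
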