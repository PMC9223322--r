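test_that("single blocks induce reentry exactly when the return loop reaches tau", {
  cfg30 <- ddm_config(tau = 30, pacing = list(type = "nodes", ids = 1L))

  ring40 <- ring_network(40)
  res <- simulate_block(ring40, node = 2, blocked_neighbour = 1, cfg30)
  expect_true(res$reentry)
  expect_equal(length(res$loop), 40)          # the full 40-cycle
  expect_equal(shortest_return_length(ring40, 2, 1), 40)

  ring20 <- ring_network(20)
  expect_false(simulate_block(ring20, 2, 1, cfg30)$reentry)
  expect_equal(shortest_return_length(ring20, 2, 1), 20)

  # trees: no alternative path, no reentry anywhere
  set.seed(1)
  tree <- manual_network(random_tree_edges(25), n = 25)
  cfgt <- ddm_config(tau = 3, pacing = "all")
  sub <- find_substrate(tree, cfgt, engine = "ddm")
  expect_equal(sub$n_substrates, 0)
  expect_equal(shortest_return_length(tree, tree$edges$to[1],
                                      tree$edges$from[1]), Inf)

  expect_error(shortest_return_length(ring20, 1, 10), "not adjacent")
})

test_that("shortest return length matches an independent graph oracle", {
  skip_if_not_installed("igraph")
  # two parallel chains of length L bridged at both ends
  L <- 8
  e <- rbind(cbind(1:(L - 1), 2:L),                 # chain A
             cbind(L + (1:(L - 1)), L + (2:L)),     # chain B
             c(1, L + 1), c(L, 2 * L))              # bridges
  net <- manual_network(e, n = 2 * L)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 2]; b <- e[k, 1]
    g <- igraph::graph_from_edgelist(as.matrix(e[-k, , drop = FALSE]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, 2 * L - igraph::vcount(g)))
    d <- igraph::distances(g, v = b, to = a)[1, 1]
    want <- if (is.finite(d)) d + 1 else Inf
    expect_equal(shortest_return_length(net, a, b), want)
  }
})

test_that("substrate detection agrees between automaton and oracle engines", {
  for (s in 1:30) {
    net <- random_small_network(s)
    for (tau in c(3, 5, 10)) {
      cfg <- ddm_config(tau = tau, pacing = list(type = "nodes", ids = 1L))
      o <- find_substrate(net, cfg, engine = "oracle", collect = "none")
      d <- find_substrate(net, cfg, engine = "ddm", collect = "none")
      expect_identical(o$pairs$evaluated, d$pairs$evaluated)
      expect_identical(o$pairs$reentry, d$pairs$reentry)
    }
  }
})

test_that("substrate shrinks with tau and vanishes on acyclic networks", {
  for (s in c(2, 5, 9)) {
    net <- random_small_network(s)
    cfg <- function(tau) ddm_config(tau = tau, pacing = "all")
    subs <- lapply(c(3, 5, 10), function(tau)
      find_substrate(net, cfg(tau), collect = "none"))
    r3 <- subs[[1]]$pairs$reentry
    r5 <- subs[[2]]$pairs$reentry
    r10 <- subs[[3]]$pairs$reentry
    expect_true(all(r10 <= r5))  # tau2 >= tau1 => substrate(tau2) subset
    expect_true(all(r5 <= r3))
  }
  chain <- chain_network(30)
  for (tau in c(2, 5, 20))
    expect_equal(find_substrate(chain, ddm_config(tau = tau, pacing = "all"),
                                collect = "none")$n_substrates, 0)
})

test_that("adding an edge can abolish reentry by shortening return paths", {
  # a 12-ring sustains reentry at tau = 10; a chord splitting it into two
  # short loops removes every long return path (too much coupling protects)
  ring <- ring_network(12)
  cfg <- ddm_config(tau = 10, pacing = "all")
  expect_gt(find_substrate(ring, cfg, collect = "none")$n_substrates, 0)
  chorded <- manual_network(rbind(cbind(1:12, c(2:12, 1)), c(1, 7)), n = 12)
  expect_equal(find_substrate(chorded, cfg, collect = "none")$n_substrates, 0)
})

test_that("pacing controls which block sites are evaluated", {
  # two components: a ring and a chain; pacing in the chain never reaches
  # the ring, so its blocks are not evaluated
  e <- rbind(cbind(1:9, c(2:10, 1)[1:9]), c(10, 1), cbind(11:14, 12:15))
  net <- manual_network(e, n = 15)
  cfg <- ddm_config(tau = 3, pacing = list(type = "nodes", ids = 11L))
  sub <- find_substrate(net, cfg, collect = "none")
  ring_pairs <- sub$pairs$blocked_neighbour <= 10
  expect_true(all(!sub$pairs$evaluated[ring_pairs]))
  expect_equal(sub$n_substrates, 0)
  expect_warning(simulate_block(net, 2, 1, cfg), "does not reach")

  cfg_all <- ddm_config(tau = 3, pacing = "all")
  sub_all <- find_substrate(net, cfg_all, collect = "none")
  expect_gt(sub_all$n_substrates, 0)
})

test_that("circuits and per-voxel counts are consistent", {
  ring <- ring_network(15)
  cfg <- ddm_config(tau = 10, pacing = "all")
  sub <- find_substrate(ring, cfg, collect = "all")
  expect_gt(sub$n_substrates, 0)
  expect_equal(length(sub$circuits), sub$n_substrates)
  for (loop in sub$circuits) expect_gte(length(loop), cfg$tau)
  # every circuit touches all 15 single-node voxels of the ring
  expect_equal(sum(sub$per_voxel_counts), sub$n_substrates * 15)
  # dense short-loop network: girth < tau and all returns short => empty
  full <- manual_network(t(combn(6, 2)), n = 6)
  expect_equal(find_substrate(full, ddm_config(tau = 10, pacing = "all"),
                              collect = "none")$n_substrates, 0)
})
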