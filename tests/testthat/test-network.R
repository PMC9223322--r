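test_that("the logistic attachment law has its midpoint, tails and monotonicity", {
  # p(c; r, c) = 1/2 exactly, for any steepness and characteristic distance
  for (r in c(1, 7, 20)) for (cc in c(0.2, 1, 3))
    expect_equal(connection_probability(cc, r, cc), 0.5, tolerance = 0)
  # hand-evaluated closed form at the candidate cutoff and at contact
  expect_equal(connection_probability(2, 7, 1), 1 / (exp(7) + 1),
               tolerance = 1e-12)
  expect_equal(connection_probability(2, 7, 1), 9.110e-4, tolerance = 1e-3)
  expect_equal(connection_probability(0, 7, 1), 1 / (exp(-7) + 1),
               tolerance = 1e-12)
  expect_equal(connection_probability(0, 7, 1), 0.99909, tolerance = 1e-4)
  x <- seq(0, 3, by = 0.01)
  expect_true(all(diff(connection_probability(x, 7, 0.5)) < 0))
  expect_true(all(connection_probability(x, 7, 0.5) > 0 &
                    connection_probability(x, 7, 0.5) < 1))
  expect_error(connection_probability(-0.1, 7, 0.5), ">= 0")
})

test_that("candidate pairs match brute-force enumeration", {
  set.seed(3)
  nodes <- tibble::tibble(x = runif(200, 0, 8), y = runif(200, 0, 8),
                          z = runif(200, 0, 4))
  got <- candidate_pairs(nodes, 2)
  D <- as.matrix(dist(cbind(nodes$x, nodes$y, nodes$z)))
  want <- which(upper.tri(D) & D < 2, arr.ind = TRUE)
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$i, unname(want[, 1]))
  expect_equal(got$j, unname(want[, 2]))
  expect_equal(got$dist, D[cbind(got$i, got$j)])

  two <- tibble::tibble(x = c(0, 2.5), y = c(0, 0), z = c(0, 0))
  expect_equal(nrow(candidate_pairs(two, 2)), 0)
  expect_equal(nrow(candidate_pairs(nodes, 0.01)), 0)
})

test_that("fibre networks couple tracts longitudinally at p = 1 and transversely by distance", {
  sl <- small_slab()
  net <- build_fibre_network(sl$ts, coupling_config(c = 0.5, seed = 4))

  lon <- net$edges[net$edges$type == "longitudinal", ]
  nd <- net$nodes
  # exactly the consecutive same-tract pairs
  expected <- nd |> dplyr::arrange(tract, along) |>
    dplyr::group_by(tract) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  expect_equal(nrow(lon), sum(pmax(expected$n - 1, 0)))
  expect_true(all(nd$tract[lon$from] == nd$tract[lon$to]))
  expect_true(all(abs(nd$along[lon$from] - nd$along[lon$to]) == 1))

  # no transverse edge joins nodes of the same tract (default), none beyond
  # the cutoff, no duplicates or self loops
  tr <- net$edges[net$edges$type == "transverse", ]
  expect_true(all(nd$tract[tr$from] != nd$tract[tr$to]))
  dd <- sqrt((nd$x[tr$from] - nd$x[tr$to])^2 + (nd$y[tr$from] - nd$y[tr$to])^2 +
               (nd$z[tr$from] - nd$z[tr$to])^2)
  expect_true(all(dd < 2))
  key <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(net$edges$from != net$edges$to))

  # c -> 0 with large steepness: transverse edges vanish, leaving disjoint
  # tract chains
  net0 <- build_fibre_network(sl$ts, coupling_config(c = 1e-9, r = 60, seed = 4))
  expect_equal(sum(net0$edges$type == "transverse"), 0)

  # determinism and exact nestedness of edge sets in c (shared uniforms)
  netA <- build_fibre_network(sl$ts, coupling_config(c = 0.5, seed = 4))
  expect_identical(net$edges, netA$edges)
  net_lo <- build_fibre_network(sl$ts, coupling_config(c = 0.3, seed = 4))
  key_lo <- paste(net_lo$edges$from, net_lo$edges$to)
  expect_true(all(key_lo %in% paste(net$edges$from, net$edges$to)))
})

test_that("cross-tract connection frequency matches the logistic law at the midpoint", {
  # two straight parallel tracts one voxel apart: each cross pair at x = 1
  # connects with probability 1/2 when c = 1
  n <- 30
  nodes <- tibble::tibble(
    x = rep(seq_len(n) - 0.5, 2), y = rep(c(0.5, 1.5), each = n), z = 0.5,
    vi = rep(seq_len(n), 2L), vj = rep(c(1L, 2L), each = n), vk = 1L,
    tract = rep(1:2, each = n), along = rep(seq_len(n), 2),
    id = seq_len(2L * n))
  ts <- structure(list(nodes = nodes, tracts = list(), n_occupied = 2L * n,
                       dims = c(n, 2L, 1L),
                       params = tractography_params()), class = "tract_set")
  hits <- 0; total <- 0
  for (s in 1:40) {
    net <- build_fibre_network(ts, coupling_config(c = 1, seed = s))
    nd <- net$nodes
    tr <- net$edges[net$edges$type == "transverse", ]
    dd <- sqrt((nd$x[tr$from] - nd$x[tr$to])^2 + (nd$y[tr$from] - nd$y[tr$to])^2)
    hits <- hits + sum(abs(dd - 1) < 1e-9)
    total <- total + n # straight-across pairs at distance exactly 1
  }
  frac <- hits / total
  se <- sqrt(0.25 / total)
  expect_lt(abs(frac - 0.5), 5 * se)
})

test_that("the fibre-less null model places spaced nodes and only transverse edges", {
  fx <- make_fixture(fixture_spec("slab", dims = c(40, 30, 4), thickness = 4))
  net <- build_null_network(fx$geometry, coupling_config(c = 0.9, seed = 8))
  expect_equal(sum(net$edges$type == "longitudinal"), 0)
  pts <- cbind(net$nodes$x, net$nodes$y, net$nodes$z)
  expect_gte(min(dist(pts[sample.int(nrow(pts), 800), ])), 0) # sanity
  expect_gte(min(dist(pts)), 0.7)
  dens <- nrow(net$nodes) / n_occupied(fx$geometry)
  expect_gte(dens, 0.8); expect_lte(dens, 1.2)

  # with no permanent longitudinal edges, the null model is sparser than the
  # fibre model at the same coupling: comparable density needs larger c
  sl <- small_slab()
  fn <- build_fibre_network(sl$ts, coupling_config(c = 0.6, seed = 2))
  nn <- build_null_network(sl$fx$geometry, coupling_config(c = 0.6, seed = 2))
  expect_gt(nrow(fn$edges) / nrow(fn$nodes), nrow(nn$edges) / nrow(nn$nodes))
})
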