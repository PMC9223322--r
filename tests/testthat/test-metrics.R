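test_that("occupied voxel fraction reads bulk, surface and isolation correctly", {
  # deep voxel of a solid block: fully occupied neighbourhood
  solid <- voxel_geometry(array(TRUE, c(13, 13, 13)))
  ovf <- occupied_voxel_fraction(solid, 5)
  expect_equal(ovf[7, 7, 7], 1)

  # surface voxel of a thick slab: half-space, about one half
  slab <- voxel_geometry(array(TRUE, c(21, 21, 12)))
  ovf2 <- occupied_voxel_fraction(slab, 5)
  expect_gt(ovf2[11, 11, 12], 0.45)
  expect_lt(ovf2[11, 11, 12], 0.58)

  # isolated voxel: 1 over the lattice-ball size (515 points at r = 5,
  # verified by enumeration)
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  ovf3 <- occupied_voxel_fraction(voxel_geometry(m), 5)
  expect_equal(ovf3[6, 6, 6], 1 / 515)
  expect_true(is.na(ovf3[1, 1, 1]))
  expect_error(occupied_voxel_fraction(solid, 0), "> 0")
})

test_that("OVF is translation invariant and monotone in occupancy", {
  set.seed(2)
  pat <- array(runif(4 * 4 * 4) < 0.5, c(4, 4, 4))
  base <- array(FALSE, c(20, 20, 20))
  a <- base; a[3:6, 3:6, 3:6] <- pat
  b <- base; b[9:12, 10:13, 8:11] <- pat
  ovf_a <- occupied_voxel_fraction(voxel_geometry(a), 2)
  ovf_b <- occupied_voxel_fraction(voxel_geometry(b), 2)
  expect_equal(ovf_a[3:6, 3:6, 3:6], ovf_b[9:12, 10:13, 8:11])

  grown <- a; grown[7, 3, 3] <- TRUE
  ovf_g <- occupied_voxel_fraction(voxel_geometry(grown), 2)
  keep <- !is.na(ovf_a)
  expect_true(all(ovf_g[keep] >= ovf_a[keep]))
})

test_that("longitudinal connection fraction reflects edge-type balance", {
  # pure chain labelled longitudinal: LCF = 1 wherever defined
  chain <- manual_network(cbind(1:9, 2:10), n = 10,
                          types = rep("longitudinal", 9), model = "fibre",
                          tracts = rep(1L, 10))
  lcf <- longitudinal_connection_fraction(chain)
  expect_true(all(lcf[!is.na(lcf)] == 1))

  # 2 longitudinal + 2 transverse edges at one node: fraction 1/2
  e <- rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5))
  pos <- rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), c(2.5, 0.5, 0.5),
               c(1.5, 1.5, 0.5), c(1.5, 2.5, 0.5))
  net <- manual_network(e, n = 5, pos = pos, model = "fibre",
                        types = c("longitudinal", "longitudinal",
                                  "transverse", "transverse"),
                        tracts = c(1L, 1L, 1L, 2L, 3L))
  lcf2 <- longitudinal_connection_fraction(net)
  expect_equal(lcf2[2, 1, 1], 0.5)

  # not defined for the fibre-less null model
  null_net <- manual_network(e, n = 5, pos = pos, model = "null")
  expect_error(longitudinal_connection_fraction(null_net), "null model")

  # removing transverse edges never decreases any defined LCF value
  pruned <- net
  pruned$edges <- pruned$edges[pruned$edges$type == "longitudinal", ]
  lcf3 <- longitudinal_connection_fraction(pruned)
  both <- !is.na(lcf2) & !is.na(lcf3)
  expect_true(all(lcf3[both] >= lcf2[both]))
})

test_that("eps-clustering counts components of the eps graph", {
  # coincident points: one cluster
  expect_equal(count_eps_clusters(matrix(rep(c(3, 3, 3), 50), ncol = 3,
                                         byrow = TRUE), 10), 1)
  # two tight groups far apart: two clusters
  g1 <- matrix(rep(c(0, 0, 0), 20), ncol = 3, byrow = TRUE) + runif(60, 0, 1)
  g2 <- g1 + 50
  expect_equal(count_eps_clusters(rbind(g1, g2), 10), 2)
  # all pairwise separations above eps: every point its own cluster
  lat <- as.matrix(expand.grid(x = seq(0, 45, 15), y = seq(0, 45, 15),
                               z = seq(0, 45, 15)))
  expect_equal(count_eps_clusters(lat, 10), nrow(lat))

  # against a brute-force union-find oracle on random points
  set.seed(4)
  for (rep in 1:5) {
    pts <- matrix(runif(3 * 40, 0, 30), ncol = 3)
    for (eps in c(2, 5, 12)) {
      D <- as.matrix(dist(pts)) <= eps
      comp <- seq_len(nrow(pts))
      repeat {
        nxt <- vapply(seq_len(nrow(pts)),
                      function(i) min(comp[D[i, ]]), numeric(1))
        if (identical(nxt, comp)) break
        comp <- nxt
      }
      expect_equal(count_eps_clusters(pts, eps), length(unique(comp)))
    }
  }

  # non-increasing in eps on a fixed sample
  pts <- matrix(runif(3 * 60, 0, 40), ncol = 3)
  counts <- vapply(c(1, 3, 6, 12, 24), function(e) count_eps_clusters(pts, e),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("substrate cluster counts resample with replacement and bootstrap", {
  set.seed(6)
  vox <- rbind(matrix(1, 30, 3) + matrix(runif(90, 0, 2), 30, 3),
               matrix(60, 10, 3) + matrix(runif(30, 0, 2), 10, 3))
  cfg <- metrics_config(n_sampled_voxels = 200, n_bootstrap = 30)
  out <- substrate_cluster_count(vox, cfg, seed = 2)
  expect_equal(out$n_clusters, 2)
  expect_true(out$boot_ci[1] <= out$boot_mean &&
                out$boot_mean <= out$boot_ci[2])
  expect_length(out$boot_counts, 30)
  expect_error(substrate_cluster_count(matrix(numeric(0), 0, 3), cfg),
               "empty substrate")
})

test_that("risk-weighted distributions reduce correctly in degenerate cases", {
  set.seed(10)
  dims <- c(6, 5, 4)
  ovf <- array(runif(prod(dims), 0.2, 0.9), dims)
  lcf <- array(runif(prod(dims)), dims)

  # uniform risk: weighted distribution equals the normalized voxel counts
  unif <- array(0.01, dims)
  d1 <- risk_weighted_distribution(unif, ovf, lcf, bin_width = 0.1)
  expect_equal(d1$table$risk / sum(d1$table$risk),
               d1$table$n_voxels / sum(d1$table$n_voxels))
  expect_equal(d1$mean_ovf_substrate, d1$mean_ovf_geometry)

  # point mass: weighted mean is that voxel's (OVF, LCF)
  pm <- array(0, dims); pm[3, 2, 1] <- 0.5
  d2 <- risk_weighted_distribution(pm, ovf, lcf)
  expect_equal(unname(d2$weighted_mean["ovf"]), ovf[3, 2, 1])
  expect_equal(unname(d2$weighted_mean["lcf"]), lcf[3, 2, 1])
  expect_equal(unname(d2$percentiles$ovf["p50"]), ovf[3, 2, 1])

  # hand-summed weighted mean on a 10-voxel toy
  ovf10 <- array(NA_real_, c(10, 1, 1)); ovf10[, 1, 1] <- seq(0.1, 1, 0.1)
  rv10 <- array(0, c(10, 1, 1)); rv10[, 1, 1] <- c(1:5, 0, 0, 0, 0, 5) / 100
  d3 <- risk_weighted_distribution(rv10, ovf10)
  hand <- sum(seq(0.1, 1, 0.1) * c(1:5, 0, 0, 0, 0, 5)) / sum(c(1:5, 5))
  expect_equal(d3$mean_ovf_substrate, hand)
  expect_equal(unname(d3$weighted_mean["ovf"]), hand)

  expect_error(risk_weighted_distribution(array(0, c(2, 2, 2)), ovf), "mismatch")
})
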