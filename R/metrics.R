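#' Structural metrics configuration
#'
#' @param r_tilde radius (voxel units) of the spherical neighbourhood used
#'   by the occupied voxel fraction.
#' @param eps clustering distance (voxel units) for the substrate cluster
#'   count.
#' @param min_cluster_size minimum points per cluster (1: clusters are the
#'   connected components of the eps-neighbourhood graph).
#' @param n_sampled_voxels circuit voxels sampled for each cluster count.
#' @param n_bootstrap bootstrap resamples for the cluster-count error bar.
#' @param bin_width histogram bin width for the OVF x LCF distributions.
#' @return An object of class `metrics_config`.
#' @export
metrics_config <- function(r_tilde = 5, eps = 10, min_cluster_size = 1L,
                           n_sampled_voxels = 1000L, n_bootstrap = 100L,
                           bin_width = 0.02) {
  if (r_tilde <= 0) stop("`r_tilde` must be > 0")
  if (eps <= 0) stop("`eps` must be > 0")
  if (n_sampled_voxels < 1L) stop("`n_sampled_voxels` must be >= 1")
  structure(list(r_tilde = r_tilde, eps = eps,
                 min_cluster_size = as.integer(min_cluster_size),
                 n_sampled_voxels = as.integer(n_sampled_voxels),
                 n_bootstrap = as.integer(n_bootstrap),
                 bin_width = bin_width),
            class = "metrics_config")
}

# Integer lattice offsets with centre distance <= r (the "lattice sphere").
lattice_sphere_offsets <- function(r) {
  h <- floor(r)
  g <- expand.grid(dx = -h:h, dy = -h:h, dz = -h:h)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, ]
  as.matrix(g)
}

#' Occupied voxel fraction (OVF)
#'
#' A bulk-defined proxy for wall thickness and convexity: for each occupied
#' voxel, the number of occupied voxels whose centres lie within `r_tilde`
#' divided by the total number of lattice points within `r_tilde` — a fixed,
#' position-independent denominator. Voxels beyond the grid edge count as
#' unoccupied, so voxels near thin or convex walls genuinely read low.
#' Values lie in (0, 1]: deep bulk voxels read 1, a flat surface reads about
#' 0.5, thin protruding structures read lower still.
#'
#' @param geom a [voxel_geometry()] (non-empty).
#' @param r_tilde neighbourhood radius in voxel units.
#' @return 3-d array of OVF values at occupied voxels, `NA` elsewhere.
#' @export
occupied_voxel_fraction <- function(geom, r_tilde = 5) {
  if (r_tilde <= 0) stop("`r_tilde` must be > 0")
  if (n_occupied(geom) == 0L) stop("empty mask")
  offs <- lattice_sphere_offsets(r_tilde)
  denom <- nrow(offs)
  d <- geom$dim
  h <- floor(r_tilde)
  pd <- d + 2L * h
  pad <- array(0, pd)
  pad[h + seq_len(d[1]), h + seq_len(d[2]), h + seq_len(d[3])] <- geom$mask
  acc <- array(0, d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    acc <- acc + pad[h + o[1] + seq_len(d[1]),
                     h + o[2] + seq_len(d[2]),
                     h + o[3] + seq_len(d[3])]
  }
  out <- acc / denom
  out[!geom$mask] <- NA_real_
  out
}

#' Longitudinal connection fraction (LCF)
#'
#' A proxy for local fibre alignment in a fibre spatial network: for each
#' node, the fraction of its edges that are longitudinal (along its tract);
#' per voxel, the average over resident nodes. High LCF means well-aligned
#' fibre bundles; low LCF means disordered fibre structure. Note the
#' denominator: LCF can rise either from more longitudinal edges or from
#' fewer transverse edges.
#'
#' Not defined for the fibre-less null model (it has no longitudinal
#' edges); calling it on one is an error. The documented workaround for
#' fibre/null comparisons is to label null-model voxels with the LCF of the
#' paired fibre-model network on the same geometry.
#'
#' @param net a fibre-model `spatial_network`.
#' @return 3-d array of per-voxel LCF; `NA` where no resident node has any
#'   edge.
#' @export
longitudinal_connection_fraction <- function(net) {
  if (!identical(net$model, "fibre"))
    stop("the LCF is not defined for the fibre-less null model; ",
         "label null-model voxels with the paired fibre-model LCF instead")
  if (is.null(net$dims)) stop("network carries no grid dimensions")
  n <- nrow(net$nodes)
  deg_l <- tabulate(c(net$edges$from[net$edges$type == "longitudinal"],
                      net$edges$to[net$edges$type == "longitudinal"]), n)
  deg_t <- tabulate(c(net$edges$from[net$edges$type == "transverse"],
                      net$edges$to[net$edges$type == "transverse"]), n)
  tot <- deg_l + deg_t
  frac <- ifelse(tot > 0, deg_l / tot, NA_real_)
  li <- linear_index(cbind(net$nodes$vi, net$nodes$vj, net$nodes$vk), net$dims)
  ok <- !is.na(frac)
  sums <- tapply(frac[ok], li[ok], sum)
  cnts <- tapply(rep(1, sum(ok)), li[ok], sum)
  out <- array(NA_real_, net$dims)
  out[as.integer(names(sums))] <- as.numeric(sums) / as.numeric(cnts)
  out
}

#' Count eps-clusters of a point set
#'
#' The number of spatial clusters under density clustering with minimum
#' cluster size 1, i.e. the connected components of the graph joining points
#' at distance `<= eps` (computed as single-linkage components). Duplicate
#' points fall in the same cluster.
#'
#' @param coords numeric matrix (n x 3) of coordinates.
#' @param eps linking distance.
#' @return Integer number of clusters, between 1 and `n`.
#' @export
count_eps_clusters <- function(coords, eps) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  u <- unique(coords)
  if (nrow(u) == 1L) return(1L)
  hc <- hclust(dist(u), method = "single")
  max(cutree(hc, h = eps))
}

#' Cluster count of the micro-reentrant substrate
#'
#' Samples `n_sampled_voxels` voxels (with replacement) from the voxels
#' containing identified circuits, counts eps-clusters, and bootstraps the
#' sample for an error bar. One cluster means all sampled circuits fall in a
#' single small region; `n_sampled_voxels` clusters mean no two circuits
#' share a location.
#'
#' @param substrate_voxels matrix (n x 3) of voxel coordinates containing
#'   circuits, or the coordinates repeated per circuit (sampling weights
#'   follow row multiplicity).
#' @param cfg a [metrics_config()].
#' @param seed RNG seed.
#' @return List with `n_clusters` (point estimate from the primary sample),
#'   `boot_mean`, `boot_ci` (2.5/97.5 percentiles) and `boot_counts`.
#' @export
substrate_cluster_count <- function(substrate_voxels, cfg = metrics_config(),
                                    seed = 1L) {
  if (is.null(dim(substrate_voxels)))
    substrate_voxels <- matrix(substrate_voxels, ncol = 3)
  if (nrow(substrate_voxels) == 0L) stop("empty substrate: nothing to cluster")
  withr::with_seed(seed, {
    idx <- sample.int(nrow(substrate_voxels), cfg$n_sampled_voxels,
                      replace = TRUE)
    sampled <- substrate_voxels[idx, , drop = FALSE]
    n0 <- count_eps_clusters(sampled, cfg$eps)
    boots <- vapply(seq_len(cfg$n_bootstrap), function(b) {
      rs <- sampled[sample.int(nrow(sampled), replace = TRUE), , drop = FALSE]
      count_eps_clusters(rs, cfg$eps)
    }, numeric(1))
    list(n_clusters = n0,
         boot_mean = mean(boots),
         boot_ci = unname(quantile(boots, c(0.025, 0.975))),
         boot_counts = boots)
  })
}

#' Risk-weighted OVF x LCF distribution
#'
#' Histograms the per-voxel structural metrics (occupied voxel fraction and,
#' if available, longitudinal connection fraction), both unweighted (voxel
#' counts per bin) and weighted by local risk (summed `R_v` per bin), and
#' reports the risk-weighted mean and the 10/25/50/75/90th percentiles of
#' each axis, plus the scalar comparison of the mean OVF over substrate
#' voxels against the geometry-wide mean OVF.
#'
#' @param risk a `risk_map` (from [ensemble_risk()]) or a 3-d local-risk
#'   array.
#' @param ovf OVF array from [occupied_voxel_fraction()].
#' @param lcf optional LCF array from [longitudinal_connection_fraction()].
#' @param bin_width histogram bin width on both axes.
#' @return An object of class `risk_distribution`: tibble `table` (bin
#'   centres, voxel count, summed risk), `weighted_mean`, `percentiles`
#'   (weighted, per axis), `mean_ovf_substrate`, `mean_ovf_geometry`.
#' @export
risk_weighted_distribution <- function(risk, ovf, lcf = NULL,
                                       bin_width = 0.02) {
  rv <- if (inherits(risk, "risk_map")) risk$local_risk else risk
  if (!all(dim(rv) == dim(ovf))) stop("risk/OVF grid mismatch")
  if (!is.null(lcf) && !all(dim(lcf) == dim(ovf))) stop("LCF grid mismatch")
  keep <- !is.na(ovf)
  df <- tibble(ovf = ovf[keep], risk = rv[keep],
               lcf = if (!is.null(lcf)) lcf[keep] else NA_real_)
  bw <- bin_width
  df$ovf_bin <- (floor(df$ovf / bw) + 0.5) * bw
  df$lcf_bin <- if (!is.null(lcf)) (floor(df$lcf / bw) + 0.5) * bw else NA_real_
  tab <- df |>
    dplyr::group_by(.data$ovf_bin, .data$lcf_bin) |>
    dplyr::summarise(n_voxels = dplyr::n(), risk = sum(.data$risk),
                     .groups = "drop")
  wtot <- sum(df$risk)
  wm <- if (wtot > 0)
    c(ovf = sum(df$ovf * df$risk) / wtot,
      lcf = if (!is.null(lcf)) sum(df$lcf * df$risk, na.rm = TRUE) / wtot else NA_real_)
  else c(ovf = NA_real_, lcf = NA_real_)
  probs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  pct <- list(
    ovf = weighted_quantile(df$ovf, df$risk, probs),
    lcf = if (!is.null(lcf))
      weighted_quantile(df$lcf[!is.na(df$lcf)], df$risk[!is.na(df$lcf)], probs)
  )
  if (!is.null(pct$ovf)) names(pct$ovf) <- paste0("p", probs * 100)
  if (!is.null(pct$lcf)) names(pct$lcf) <- paste0("p", probs * 100)
  structure(list(
    table = tab,
    weighted_mean = wm,
    percentiles = pct,
    mean_ovf_substrate = if (wtot > 0) sum(df$ovf * df$risk) / wtot else NA_real_,
    mean_ovf_geometry = mean(df$ovf),
    bin_width = bw
  ), class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("<risk_distribution> mean OVF: substrate %.3f vs geometry %.3f\n",
              x$mean_ovf_substrate, x$mean_ovf_geometry))
  invisible(x)
}
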