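#' Global risk of micro-anatomical reentry
#'
#' The rate at which unidirectional conduction blocks initiate reentry under
#' uniform block susceptibility: the number of reentry-inducing blocks `N`
#' divided by the number of block opportunities evaluated. Directly
#' proportional to the substrate count `N` at fixed network size, and always
#' in `[0, 1]` (a per-block induction probability).
#'
#' @param result a [find_substrate()] result.
#' @return The global risk rate `lambda`.
#' @export
estimate_global_risk <- function(result) {
  stopifnot(inherits(result, "substrate_result"))
  if (result$n_evaluated == 0L)
    stop("no block opportunities were evaluated (empty or unpaced network)")
  result$n_substrates / result$n_evaluated
}

#' Local risk map from circuit counts
#'
#' Apportions the global risk `lambda` to voxels by their share of
#' identified circuits: `R_v = lambda * N_v / sum_v N_v`, so that the local
#' risk sums back to `lambda` exactly.
#'
#' @param counts per-voxel circuit counts (3-d array), `N_v`.
#' @param lambda_ global risk rate.
#' @return 3-d array of local risk, same shape as `counts`.
#' @export
local_risk <- function(counts, lambda_) {
  if (lambda_ < 0) stop("`lambda_` must be >= 0")
  tot <- sum(counts)
  if (tot == 0) {
    if (lambda_ > 0) stop("lambda > 0 but all circuit counts are zero")
    return(array(0, dim(counts)))
  }
  lambda_ * counts / tot
}

#' Gaussian smoothing of a voxel map
#'
#' Isotropic 3-d Gaussian convolution on the voxel grid, used only for map
#' display: never applied before computing `lambda` or cluster statistics.
#' The kernel is truncated at 4 sigma and the map total is renormalized, so
#' the summed risk is preserved. `sigma = 0` is the identity.
#'
#' @param map 3-d numeric array (NAs treated as zero).
#' @param sigma standard deviation in voxels, >= 0.
#' @return Smoothed array with the same total.
#' @export
smooth_map <- function(map, sigma = 5) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(map)
  map[is.na(map)] <- 0
  total <- sum(map)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  d <- dim(map)
  conv_axis <- function(arr, axis) {
    n <- d[axis]
    K <- matrix(0, n, n)
    for (off in -half:half) {
      ix <- seq_len(n)
      jx <- ix + off
      ok <- jx >= 1 & jx <= n
      K[cbind(ix[ok], jx[ok])] <- K[cbind(ix[ok], jx[ok])] + k[off + half + 1]
    }
    # normalized boundary handling: each output voxel averages over the part
    # of the kernel inside the grid, so constants are preserved exactly
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dim(a) <- c(n, prod(d[-axis]))
    a <- K %*% a
    dim(a) <- d[perm]
    aperm(a, order(perm))
  }
  out <- conv_axis(conv_axis(conv_axis(map, 1), 2), 3)
  s <- sum(out)
  if (s > 0) out <- out * (total / s)
  out
}

new_risk_map <- function(lambda_, counts, ensemble_size, sigma, provenance,
                         lambda_per_network = NULL, anchor_counts = NULL) {
  lr <- local_risk(counts, lambda_)
  structure(list(
    lambda = lambda_, counts = counts, local_risk = lr,
    smoothed = if (!is.null(sigma) && sigma > 0) smooth_map(lr, sigma),
    sigma = sigma, ensemble_size = ensemble_size,
    lambda_per_network = lambda_per_network,
    anchor_counts = anchor_counts, provenance = provenance
  ), class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  cat(sprintf("<risk_map> lambda = %.5f over %d network(s); %d voxels at risk\n",
              x$lambda, x$ensemble_size, sum(x$counts > 0)))
  invisible(x)
}

#' Ensemble risk map
#'
#' Generates an ensemble of independent random spatial networks on one
#' geometry (fresh coupling randomness per member; for the fibre model the
#' tract set is fixed by default, or regenerated per member), identifies the
#' micro-reentrant substrate of each, samples a fixed number of identified
#' circuits per network, and pools their per-voxel counts. The global risk
#' `lambda` is averaged across the ensemble and the pooled counts are turned
#' into a local risk map via [local_risk()]. Fully seeded: a master seed
#' determines every stage.
#'
#' @param geom a [voxel_geometry()].
#' @param field an [orientation_field()] (fibre model) or `NULL` (null
#'   model).
#' @param model `"fibre"` or `"null"`.
#' @param coupling a [coupling_config()]; its `seed` is ignored in favour of
#'   the ensemble seed stream.
#' @param ddm a [ddm_config()].
#' @param n_networks ensemble size.
#' @param n_circuits circuits sampled (with replacement, uniformly over
#'   reentry-inducing blocks) per network for the local risk counts.
#' @param tract_params a [tractography_params()] (fibre model).
#' @param tracts optional pre-computed [generate_tract_set()] result; if
#'   `NULL` and `regenerate_tracts = FALSE`, tracts are generated once.
#' @param regenerate_tracts regenerate the tract set for every ensemble
#'   member (slower; propagates tractography variability).
#' @param sigma Gaussian display smoothing in voxels (applied to a copy;
#'   `lambda` and counts stay unsmoothed).
#' @param seed master seed.
#' @return A `risk_map` with fields `lambda` (ensemble mean), `counts`
#'   (pooled `N_v`: circuits intersecting each voxel), `anchor_counts`
#'   (circuits whose block site sits in each voxel — the localized anchor of
#'   a circuit, useful when loop extents are large relative to the
#'   geometry), `local_risk`, `smoothed`, `lambda_per_network`,
#'   `ensemble_size` and `provenance`.
#' @export
ensemble_risk <- function(geom, field = NULL, model = c("fibre", "null"),
                          coupling = coupling_config(), ddm = ddm_config(),
                          n_networks = 50L, n_circuits = 1000L,
                          tract_params = tractography_params(),
                          tracts = NULL, regenerate_tracts = FALSE,
                          sigma = 5, seed = 1L) {
  model <- match.arg(model)
  if (n_networks < 1L) stop("`n_networks` must be >= 1")
  seeds <- derive_seeds(seed, 3L * n_networks + 1L)
  if (model == "fibre" && is.null(tracts) && !regenerate_tracts) {
    tp <- tract_params; tp$seed <- seeds[3L * n_networks + 1L]
    tracts <- generate_tract_set(geom, field, tp)
  }
  skel <- if (model == "fibre" && !regenerate_tracts)
    network_skeleton(tracts, coupling$cutoff)

  counts <- array(0, geom$dim)
  anchors <- array(0, geom$dim)
  lambda_k <- numeric(n_networks)
  for (k in seq_len(n_networks)) {
    if (model == "fibre") {
      if (regenerate_tracts) {
        tp <- tract_params; tp$seed <- seeds[3L * k - 2L]
        tracts_k <- generate_tract_set(geom, field, tp)
        skel_k <- network_skeleton(tracts_k, coupling$cutoff)
      } else skel_k <- skel
      tr <- realise_edges(skel_k, coupling$c, coupling$r, seeds[3L * k - 1L])
      edges <- dplyr::bind_rows(
        tibble(from = skel_k$lon_edges$from, to = skel_k$lon_edges$to,
               type = "longitudinal"),
        tibble(from = tr$from, to = tr$to, type = "transverse"))
      net <- new_spatial_network(skel_k$nodes, edges, "fibre", coupling,
                                 extra = list(dims = geom$dim))
    } else {
      cfg_k <- coupling; cfg_k$seed <- seeds[3L * k - 1L]
      net <- build_null_network(geom, cfg_k, d_sep = tract_params$d_sep)
    }
    sub <- find_substrate(net, ddm, engine = "oracle", collect = "none")
    lambda_k[k] <- if (sub$n_evaluated > 0) estimate_global_risk(sub) else 0
    if (sub$n_substrates > 0L) {
      picks <- withr::with_seed(seeds[3L * k],
        sub$circuit_pairs[sample.int(length(sub$circuit_pairs), n_circuits,
                                     replace = TRUE)])
      tab <- table(picks)
      uniq <- as.integer(names(tab))
      circ <- extract_circuits(net, uniq)
      counts <- counts + circuit_voxel_counts(net, circ,
                                              weights = as.numeric(tab),
                                              dims = geom$dim)
      # anchor (block-site) voxel of each sampled circuit
      e_ <- uniq %/% 2L; d_ <- uniq %% 2L
      a_ <- ifelse(d_ == 0L, net$edges$to[e_ + 1L], net$edges$from[e_ + 1L])
      ali <- linear_index(cbind(net$nodes$vi[a_], net$nodes$vj[a_],
                                net$nodes$vk[a_]), geom$dim)
      for (q in seq_along(ali))
        anchors[ali[q]] <- anchors[ali[q]] + as.numeric(tab)[q]
    }
  }
  new_risk_map(mean(lambda_k), counts, n_networks, sigma,
               anchor_counts = anchors,
               provenance = list(model = model, c = coupling$c,
                                 r = coupling$r, cutoff = coupling$cutoff,
                                 tau = ddm$tau, n_circuits = n_circuits,
                                 seed = seed),
               lambda_per_network = lambda_k)
}
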