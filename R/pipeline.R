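# Orchestration: configured end-to-end runs and c-calibration sweeps.

#' Assemble a run configuration
#'
#' A `run_config` describes one reproducible end-to-end run: input geometry
#' (a fixture spec or a file path), models, coupling grid, and the
#' sub-configurations of every stage. Every stochastic stage derives its
#' seed deterministically from the master seed. Configurations round-trip
#' losslessly through YAML ([read_run_config()] / [write_run_config()]).
#'
#' @param fixture list of arguments to [fixture_spec()], or `NULL` when
#'   `geometry_path` is given.
#' @param geometry_path path stem readable by [read_geometry()].
#' @param geometry_format `"rds"` or `"nifti"`.
#' @param model `"fibre"`, `"null"` or `"both"`.
#' @param c_values numeric vector of characteristic couplings (>= 1 value).
#' @param r,cutoff coupling law parameters.
#' @param tractography list of arguments to [tractography_params()].
#' @param ddm list of arguments to [ddm_config()].
#' @param metrics list of arguments to [metrics_config()].
#' @param n_networks,n_circuits,sigma ensemble settings (see
#'   [ensemble_risk()]).
#' @param seed master seed.
#' @param out_dir output directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fixture = list(kind = "slab"), geometry_path = NULL,
                       geometry_format = "rds", model = "fibre",
                       c_values = c(0.4), r = 7, cutoff = 2,
                       tractography = list(), ddm = list(), metrics = list(),
                       n_networks = 10L, n_circuits = 200L, sigma = 5,
                       seed = 1L, out_dir = tempfile("fibrenet_run")) {
  if (!model %in% c("fibre", "null", "both")) stop("unknown `model`")
  if (length(c_values) < 1L || !is.numeric(c_values))
    stop("`c_values` must contain at least one coupling value")
  structure(list(fixture = fixture, geometry_path = geometry_path,
                 geometry_format = geometry_format, model = model,
                 c_values = as.numeric(c_values), r = r, cutoff = cutoff,
                 tractography = tractography, ddm = ddm, metrics = metrics,
                 n_networks = as.integer(n_networks),
                 n_circuits = as.integer(n_circuits), sigma = sigma,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$out_dir <- x$out_dir %||% tempfile("fibrenet_run")
  do.call(run_config, x)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

resolve_geometry <- function(cfg) {
  if (!is.null(cfg$geometry_path)) {
    read_geometry(cfg$geometry_path, cfg$geometry_format)
  } else {
    make_fixture(do.call(fixture_spec, cfg$fixture))
  }
}

# Sample circuit voxels (prob ~ pooled counts) and count eps-clusters,
# with a bootstrap error bar.
cluster_from_counts <- function(counts, metrics = metrics_config(), seed = 1L) {
  if (sum(counts) == 0)
    return(list(n_clusters = NA_real_, boot_mean = NA_real_,
                boot_ci = c(NA_real_, NA_real_)))
  idx <- which(counts > 0, arr.ind = TRUE)
  w <- counts[counts > 0]
  withr::with_seed(seed, {
    pick <- sample.int(nrow(idx), metrics$n_sampled_voxels, replace = TRUE,
                       prob = w)
    sampled <- idx[pick, , drop = FALSE]
    n0 <- count_eps_clusters(sampled, metrics$eps)
    boots <- vapply(seq_len(metrics$n_bootstrap), function(b) {
      rs <- sampled[sample.int(nrow(sampled), replace = TRUE), , drop = FALSE]
      count_eps_clusters(rs, metrics$eps)
    }, numeric(1))
    list(n_clusters = n0, boot_mean = mean(boots),
         boot_ci = unname(quantile(boots, c(0.025, 0.975))))
  })
}

#' Calibration sweep over the characteristic coupling
#'
#' Maps the coupling grade `c` to global risk and structural summaries on
#' one geometry: for each model and each `c`, an ensemble of networks is
#' generated (fibre: fixed tract set, fresh transverse edges per member;
#' null: fixed node placement, fresh edges per member — one uniform variate
#' per candidate pair, shared across the `c` grid, so edge sets are nested
#' in `c`), the substrate is identified, circuits are sampled and pooled,
#' and the table reports `lambda` (mean and standard error), substrate
#' counts, the bootstrap cluster count and the mean OVF over substrate
#' voxels. Rows are labelled low/medium/high risk by `lambda` terciles
#' within each model, standing in for dataset-specific coupling tables.
#'
#' @param geom a [voxel_geometry()].
#' @param field an [orientation_field()] (needed for the fibre model).
#' @param c_grid numeric vector of couplings (>= 2 values).
#' @param models subset of `c("fibre", "null")`.
#' @param r,cutoff coupling law parameters.
#' @param ddm a [ddm_config()].
#' @param n_networks ensemble size per (model, c).
#' @param n_circuits circuits sampled per network member.
#' @param tract_params a [tractography_params()].
#' @param tracts optional precomputed tract set.
#' @param metrics a [metrics_config()].
#' @param n_cluster_samples circuit voxels sampled per ensemble member for
#'   its cluster count. Default (`NULL`) matches the sampling density of the
#'   full-scale analysis (about one sample per 1500 tissue voxels, at least
#'   8): the cluster count discriminates concentrated from dispersed
#'   substrate only when the sample spacing is comparable to `eps`, so the
#'   sample size must scale with the geometry.
#' @param seed master seed.
#' @return A tibble with one row per (model, c): `lambda_mean`, `lambda_se`,
#'   `n_substrates_mean`, `n_evaluated_mean`, `cluster_boot_mean`,
#'   `cluster_lo`, `cluster_hi`, `mean_substrate_ovf`, `n_substrate_voxels`,
#'   `risk_label`; attributes `mean_ovf_geometry`, `counts` (per-row pooled
#'   count arrays) and `n_nodes`.
#' @export
calibration_sweep <- function(geom, field = NULL, c_grid,
                              models = c("fibre", "null"), r = 7, cutoff = 2,
                              ddm = ddm_config(), n_networks = 50L,
                              n_circuits = 200L,
                              tract_params = tractography_params(),
                              tracts = NULL, metrics = metrics_config(),
                              n_cluster_samples = NULL, seed = 1L) {
  if (length(c_grid) < 2L) stop("`c_grid` needs at least 2 values")
  models <- match.arg(models, several.ok = TRUE)
  ovf <- occupied_voxel_fraction(geom, metrics$r_tilde)
  n_cl <- n_cluster_samples %||%
    min(metrics$n_sampled_voxels, max(8L, round(n_occupied(geom) / 1500)))
  seeds <- derive_seeds(seed, 4L)
  rows <- list()
  count_store <- list()
  n_nodes <- NA_integer_

  for (model in models) {
    if (model == "fibre") {
      if (is.null(field)) stop("fibre model requires an orientation field")
      if (is.null(tracts)) {
        tp <- tract_params; tp$seed <- seeds[1]
        tracts <- generate_tract_set(geom, field, tp)
      }
      skel <- network_skeleton(tracts, cutoff)
      nodes <- skel$nodes
    } else {
      nodes_pts <- withr::with_seed(seeds[2],
        sample_seed_points(geom, tract_params$d_sep, n = n_occupied(geom)))
      vox <- position_to_voxel(nodes_pts)
      nodes <- tibble(x = nodes_pts[, 1], y = nodes_pts[, 2], z = nodes_pts[, 3],
                      vi = vox[, 1], vj = vox[, 2], vk = vox[, 3],
                      tract = NA_integer_, along = NA_integer_,
                      id = seq_len(nrow(nodes_pts)))
      skel <- list(nodes = nodes, cand = candidate_pairs(nodes, cutoff),
                   lon_edges = tibble(from = integer(), to = integer()))
    }
    n_nodes <- nrow(nodes)
    net_seeds <- derive_seeds(seeds[3] + match(model, c("fibre", "null")),
                              2L * n_networks)
    lam <- matrix(0, n_networks, length(c_grid))
    nsub <- matrix(0, n_networks, length(c_grid))
    nev <- matrix(0, n_networks, length(c_grid))
    ncl <- matrix(NA_real_, n_networks, length(c_grid))
    counts_c <- lapply(c_grid, function(.) array(0, geom$dim))
    anchors_c <- lapply(c_grid, function(.) array(0, geom$dim))

    # fast path: everything c-independent is precomputed; per (member, c) we
    # threshold the shared uniforms and call the scan kernel directly
    nn <- nrow(nodes)
    lon_u <- as.integer(skel$lon_edges$from - 1L)
    lon_v <- as.integer(skel$lon_edges$to - 1L)
    cand_i <- as.integer(skel$cand$i - 1L)
    cand_j <- as.integer(skel$cand$j - 1L)
    pmat <- vapply(c_grid, function(cc)
      connection_probability(skel$cand$dist, r = r, c = cc),
      numeric(nrow(skel$cand)))
    pace0 <- as.integer(pacing_nodes(list(nodes = nodes), ddm$pacing) - 1L)
    vox_mat <- cbind(nodes$vi, nodes$vj, nodes$vk)

    for (k in seq_len(n_networks)) {
      u <- withr::with_seed(net_seeds[2L * k - 1L], runif(nrow(skel$cand)))
      samp_seeds <- derive_seeds(net_seeds[2L * k], 2L * length(c_grid))
      for (ci in seq_along(c_grid)) {
        keep <- u < pmat[, ci]
        eu <- c(lon_u, cand_i[keep])
        ev <- c(lon_v, cand_j[keep])
        if (length(eu) == 0L) next
        status <- ddm_oracle_scan_cpp(nn, eu, ev, ddm$tau, pace0)
        nev[k, ci] <- sum(status >= 0L)
        nsub[k, ci] <- sum(status == 1L)
        lam[k, ci] <- if (nev[k, ci] > 0) nsub[k, ci] / nev[k, ci] else 0
        if (nsub[k, ci] > 0L) {
          reentry_pairs <- which(status == 1L) - 1L
          picks <- withr::with_seed(samp_seeds[2L * ci - 1L],
            reentry_pairs[sample.int(length(reentry_pairs), n_circuits,
                                     replace = TRUE)])
          tab <- table(picks)
          uniq <- as.integer(names(tab))
          circ <- ddm_return_paths_cpp(nn, eu, ev, uniq)
          wts <- as.numeric(tab)
          member_counts <- array(0, geom$dim)
          for (li_c in seq_along(circ)) {
            lic <- unique(linear_index(vox_mat[circ[[li_c]], , drop = FALSE],
                                       geom$dim))
            member_counts[lic] <- member_counts[lic] + wts[li_c]
          }
          counts_c[[ci]] <- counts_c[[ci]] + member_counts
          # anchor (block-site) voxel of each sampled circuit
          e_ <- uniq %/% 2L; d_ <- uniq %% 2L
          a_ <- ifelse(d_ == 0L, ev[e_ + 1L], eu[e_ + 1L]) + 1L
          ali <- linear_index(vox_mat[a_, , drop = FALSE], geom$dim)
          member_anchors <- array(0, geom$dim)
          for (q in seq_along(ali))
            member_anchors[ali[q]] <- member_anchors[ali[q]] + wts[q]
          anchors_c[[ci]] <- anchors_c[[ci]] + member_anchors
          # per-member cluster count of its own sampled circuit anchors
          midx <- which(member_anchors > 0, arr.ind = TRUE)
          mcl <- withr::with_seed(samp_seeds[2L * ci], {
            pick <- sample.int(nrow(midx), n_cl, replace = TRUE,
                               prob = member_anchors[member_anchors > 0])
            count_eps_clusters(midx[pick, , drop = FALSE], metrics$eps)
          })
          ncl[k, ci] <- mcl
        }
      }
    }

    for (ci in seq_along(c_grid)) {
      det <- counts_c[[ci]] > 0
      cl_k <- ncl[, ci][!is.na(ncl[, ci])]
      boot <- if (length(cl_k) > 0)
        withr::with_seed(seeds[4] + ci, vapply(seq_len(metrics$n_bootstrap),
          function(b) mean(cl_k[sample.int(length(cl_k), replace = TRUE)]),
          numeric(1)))
      rows[[length(rows) + 1L]] <- tibble(
        model = model, c = c_grid[ci],
        lambda_mean = mean(lam[, ci]),
        lambda_se = sd(lam[, ci]) / sqrt(n_networks),
        n_substrates_mean = mean(nsub[, ci]),
        n_evaluated_mean = mean(nev[, ci]),
        cluster_boot_mean = if (length(cl_k)) mean(boot) else NA_real_,
        cluster_lo = if (length(cl_k)) unname(quantile(boot, 0.025)) else NA_real_,
        cluster_hi = if (length(cl_k)) unname(quantile(boot, 0.975)) else NA_real_,
        mean_substrate_ovf = if (sum(anchors_c[[ci]]) > 0)
          sum(ovf * anchors_c[[ci]], na.rm = TRUE) / sum(anchors_c[[ci]])
        else NA_real_,
        n_substrate_voxels = sum(det))
      count_store[[paste(model, ci)]] <- counts_c[[ci]]
      count_store[[paste(model, ci, "anchors")]] <- anchors_c[[ci]]
    }
  }

  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$model) |>
    dplyr::mutate(risk_label = c("low", "medium", "high")[
      dplyr::ntile(.data$lambda_mean, 3)]) |>
    dplyr::ungroup()
  attr(out, "mean_ovf_geometry") <- mean(ovf, na.rm = TRUE)
  attr(out, "counts") <- count_store
  attr(out, "n_nodes") <- n_nodes
  out
}

#' Run the full pipeline from a configuration
#'
#' Executes fixture/load -> tractography -> network ensembles -> substrate
#' detection -> risk mapping -> structural metrics for every requested
#' (model, c), writes every intermediate artifact under `cfg$out_dir`, and
#' returns (and writes) a manifest with summary statistics and provenance.
#' Re-running the same configuration reproduces all artifacts bit-exactly.
#'
#' @param cfg a [run_config()].
#' @return The manifest (list) invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  fx <- stage("input", resolve_geometry(cfg))
  geom <- fx$geometry; field <- fx$field
  artifacts <- character()
  gfile <- file.path(cfg$out_dir, "geometry")
  artifacts <- c(artifacts, stage("geometry_io",
    write_geometry(geom, field, gfile, format = cfg$geometry_format)))

  seeds <- derive_seeds(cfg$seed, 4L)
  models <- if (cfg$model == "both") c("fibre", "null") else cfg$model
  ddm <- do.call(ddm_config, cfg$ddm)
  metrics <- do.call(metrics_config, cfg$metrics)
  tp <- do.call(tractography_params, cfg$tractography)
  tp$seed <- seeds[1]

  tracts <- NULL
  if ("fibre" %in% models) {
    if (is.null(field)) stop("fibre model requires an orientation field")
    tracts <- stage("tractography", generate_tract_set(geom, field, tp))
    ft <- file.path(cfg$out_dir, "tract_nodes.csv")
    utils::write.csv(tracts$nodes, ft, row.names = FALSE)
    artifacts <- c(artifacts, ft)
  }
  ovf <- stage("metrics", occupied_voxel_fraction(geom, metrics$r_tilde))

  summary_rows <- list()
  for (model in models) for (cc in cfg$c_values) {
    coup <- coupling_config(cc, cfg$r, cfg$cutoff, seed = seeds[2])
    rm_ <- stage("risk", ensemble_risk(
      geom, field, model = model, coupling = coup, ddm = ddm,
      n_networks = cfg$n_networks, n_circuits = cfg$n_circuits,
      tract_params = tp, tracts = if (model == "fibre") tracts,
      sigma = cfg$sigma, seed = seeds[3] + round(1000 * cc)))
    tag <- sprintf("%s_c%s", model, format(cc))
    frisk <- file.path(cfg$out_dir, paste0("risk_", tag, ".rds"))
    saveRDS(rm_[c("lambda", "counts", "local_risk", "sigma", "provenance")],
            frisk)
    artifacts <- c(artifacts, frisk)
    cl <- cluster_from_counts(rm_$counts, metrics, seed = seeds[4])
    det <- rm_$counts > 0
    summary_rows[[tag]] <- tibble(
      model = model, c = cc, lambda = rm_$lambda,
      n_clusters = cl$boot_mean,
      mean_substrate_ovf = if (any(det)) mean(ovf[det], na.rm = TRUE) else NA_real_,
      mean_ovf_geometry = mean(ovf, na.rm = TRUE),
      n_substrate_voxels = sum(det))
  }
  summary_tbl <- dplyr::bind_rows(summary_rows)
  fs <- file.path(cfg$out_dir, "summary.csv")
  utils::write.csv(summary_tbl, fs, row.names = FALSE)
  artifacts <- c(artifacts, fs)

  manifest <- list(
    config = unclass(cfg),
    artifacts = unname(artifacts),
    summary = summary_tbl,
    provenance = list(seed = cfg$seed, derived_seeds = seeds,
                      package = "fibrenet",
                      version = as.character(utils::packageVersion("fibrenet"))))
  fm <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}
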