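# broom-style tidiers for the package's result objects.

#' Tidy a spatial network
#'
#' @param x a `spatial_network`.
#' @param ... unused.
#' @return Edge-level tibble with endpoint positions, edge type and length.
#' @export
tidy.spatial_network <- function(x, ...) {
  n <- x$nodes
  x$edges |>
    dplyr::mutate(
      length = sqrt((n$x[.data$from] - n$x[.data$to])^2 +
                      (n$y[.data$from] - n$y[.data$to])^2 +
                      (n$z[.data$from] - n$z[.data$to])^2)) |>
    as_tibble()
}

#' @rdname tidy.spatial_network
#' @export
glance.spatial_network <- function(x, ...) {
  tibble(model = x$model,
         n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges),
         n_longitudinal = sum(x$edges$type == "longitudinal"),
         n_transverse = sum(x$edges$type == "transverse"),
         c = x$config$c %||% NA_real_,
         r = x$config$r %||% NA_real_)
}

#' Tidy a substrate result
#'
#' @param x a `substrate_result`.
#' @param ... unused.
#' @return One row per evaluated directed block with its reentry flag.
#' @export
tidy.substrate_result <- function(x, ...) {
  dplyr::filter(x$pairs, .data$evaluated)
}

#' @rdname tidy.substrate_result
#' @export
glance.substrate_result <- function(x, ...) {
  tibble(n_substrates = x$n_substrates, n_evaluated = x$n_evaluated,
         n_substrate_nodes = length(x$substrate_nodes), tau = x$tau,
         lambda = if (x$n_evaluated > 0) x$n_substrates / x$n_evaluated else NA_real_)
}

#' Tidy a risk map
#'
#' @param x a `risk_map`.
#' @param ... unused.
#' @return Voxel-level tibble of circuit counts and local risk (voxels with
#'   any identified circuit).
#' @export
tidy.risk_map <- function(x, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  li <- linear_index(idx, dim(x$counts))
  tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
         n_circuits = x$counts[li], local_risk = x$local_risk[li])
}

#' @rdname tidy.risk_map
#' @export
glance.risk_map <- function(x, ...) {
  tibble(lambda = x$lambda, ensemble_size = x$ensemble_size,
         n_substrate_voxels = sum(x$counts > 0),
         total_local_risk = sum(x$local_risk),
         lambda_se = if (!is.null(x$lambda_per_network))
           sd(x$lambda_per_network) / sqrt(x$ensemble_size) else NA_real_)
}
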