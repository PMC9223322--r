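# ggplot2 displays for result objects.

#' Plot a risk map slice
#'
#' Mid-thickness slice of the (smoothed, if available) local risk map.
#' @param object a `risk_map`.
#' @param k slice index along z (default: mid-slice of detected risk).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.risk_map <- function(object, k = NULL, ...) {
  m <- object$smoothed %||% object$local_risk
  if (is.null(k)) {
    kz <- which(apply(object$counts, 3, sum) > 0)
    k <- if (length(kz)) kz[ceiling(length(kz) / 2)] else ceiling(dim(m)[3] / 2)
  }
  df <- expand.grid(i = seq_len(dim(m)[1]), j = seq_len(dim(m)[2]))
  df$risk <- as.vector(m[, , k])
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$risk)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "local risk") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Local reentry risk, slice k = %d (lambda = %.4f)",
                                  k, object$lambda),
                  x = "x (voxels)", y = "y (voxels)")
}

#' Plot a risk-weighted OVF x LCF distribution
#'
#' @param object a `risk_distribution`.
#' @param weighted show the risk-weighted (`TRUE`) or voxel-count
#'   distribution.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.risk_distribution <- function(object, weighted = TRUE, ...) {
  tab <- object$table
  fill <- if (weighted) tab$risk else tab$n_voxels
  tab$fill <- fill
  has_lcf <- !all(is.na(tab$lcf_bin))
  if (has_lcf) {
    ggplot2::ggplot(tab, ggplot2::aes(.data$ovf_bin, .data$lcf_bin,
                                      fill = .data$fill)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = if (weighted) "summed risk" else "voxels") +
      ggplot2::labs(x = "occupied voxel fraction", y = "longitudinal connection fraction")
  } else {
    ggplot2::ggplot(tab, ggplot2::aes(.data$ovf_bin, .data$fill)) +
      ggplot2::geom_col(width = object$bin_width) +
      ggplot2::labs(x = "occupied voxel fraction",
                    y = if (weighted) "summed local risk" else "voxels")
  }
}

#' Plot a calibration sweep
#'
#' Global risk against the coupling grade `c` for each model, with standard
#' errors: the band structure (risk vanishing at both strong and vanishing
#' coupling with an intermediate maximum) is the signature of a
#' characteristic fibrosis density range.
#' @param sweep a [calibration_sweep()] table.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$c, .data$lambda_mean,
                                      colour = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$lambda_mean - .data$lambda_se,
      ymax = .data$lambda_mean + .data$lambda_se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "characteristic coupling c (voxels)",
                  y = "global risk lambda")
}
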