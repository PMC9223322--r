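#' Voxel geometry
#'
#' A `voxel_geometry` is the spatial canvas for the whole pipeline: a 3-d
#' logical occupancy mask (`TRUE` = tissue) together with the physical edge
#' length of a voxel and the physical coordinate of voxel `(0,0,0)`. All
#' distances elsewhere in the package are expressed in voxel units
#' (1.0 = one voxel edge); `spacing` only records the physical scale
#' (e.g. 300 micrometres for typical atrial imaging).
#'
#' @param mask 3-d logical (or 0/1) array; `TRUE` marks tissue voxels.
#' @param spacing physical edge length of a voxel, micrometres; must be > 0.
#' @param origin physical coordinate of the corner of voxel (1,1,1),
#'   length-3 numeric.
#' @return An object of class `voxel_geometry` with fields `mask`, `spacing`,
#'   `origin` and `dim`.
#' @examples
#' g <- voxel_geometry(array(TRUE, c(4, 3, 2)), spacing = 300)
#' n_occupied(g)
#' @export
voxel_geometry <- function(mask, spacing = 1, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-d array")
  if (any(dim(mask) < 1L)) stop("`mask` dimensions must all be >= 1")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1, NA))) stop("`mask` must be logical or 0/1")
    mask <- array(as.logical(mask), dim(mask))
  }
  mask[is.na(mask)] <- FALSE
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(
    list(mask = mask, spacing = as.numeric(spacing),
         origin = as.numeric(origin), dim = dim(mask)),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> %d x %d x %d, %d occupied, spacing %g\n",
              x$dim[1], x$dim[2], x$dim[3], n_occupied(x), x$spacing))
  invisible(x)
}

#' Number of occupied voxels
#' @param geom a [voxel_geometry()].
#' @return Integer count of `TRUE` voxels.
#' @export
n_occupied <- function(geom) sum(geom$mask)

#' Indices of occupied voxels
#' @param geom a [voxel_geometry()].
#' @return Integer matrix (n x 3) of 1-based voxel indices.
#' @export
occupied_voxels <- function(geom) which(geom$mask, arr.ind = TRUE)

#' @export
as_tibble.voxel_geometry <- function(x, ...) {
  idx <- occupied_voxels(x)
  tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3])
}

#' Fibre orientation field
#'
#' Per-voxel axial unit vectors giving the local fibre direction. The field
#' is axial (sign-free): `v` and `-v` describe the same orientation, as for
#' myofibre data. Vectors are defined only at occupied voxels; elsewhere, and
#' at occupied voxels where the orientation is unknown, the field is `NA`
#' ("missing").
#'
#' @param vectors 4-d numeric array `dim = c(dim(mask), 3)` of fibre vectors.
#' @param geom the [voxel_geometry()] the field lives on.
#' @param renormalize rescale non-missing vectors to unit length. If `FALSE`,
#'   non-unit vectors (beyond 1e-9) are an error.
#' @return An object of class `orientation_field` with fields `vectors`
#'   (unit vectors, canonical axial sign) and `dim`.
#' @details Zero-length vectors at occupied voxels are invalid and reported
#'   with their voxel indices. Vectors at unoccupied voxels are discarded.
#' @export
orientation_field <- function(vectors, geom, renormalize = TRUE) {
  stopifnot(inherits(geom, "voxel_geometry"))
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4-d array with last dimension 3")
  if (!all(dim(vectors)[1:3] == geom$dim))
    stop("shape mismatch between mask and vector grids")
  v <- array(as.numeric(vectors), dim(vectors))
  occ <- geom$mask
  # discard vectors outside the mask
  for (c_ in 1:3) {
    sl <- slice4(v, c_)
    sl[!occ] <- NA_real_
    v[, , , c_] <- sl
  }
  nrm <- sqrt(slice4(v, 1)^2 + slice4(v, 2)^2 + slice4(v, 3)^2)
  zero <- occ & !is.na(nrm) & nrm < 1e-12
  if (any(zero)) {
    idx <- which(zero, arr.ind = TRUE)
    shown <- head(idx, 5L)
    stop("zero-length orientation vectors at occupied voxels: ",
         paste(apply(shown, 1, paste, collapse = ","), collapse = "; "),
         if (nrow(idx) > 5L) sprintf(" (and %d more)", nrow(idx) - 5L) else "")
  }
  if (renormalize) {
    for (c_ in 1:3) v[, , , c_] <- slice4(v, c_) / nrm
  } else {
    bad <- occ & !is.na(nrm) & abs(nrm - 1) > 1e-9
    if (any(bad)) stop("orientation vectors must be unit length (tol 1e-9)")
  }
  v <- canonical_axial(v)
  structure(list(vectors = v, dim = geom$dim, axial = TRUE),
            class = "orientation_field")
}

# Canonical sign for axial vectors: first non-zero component positive.
canonical_axial <- function(v) {
  s <- sign(slice4(v, 1))
  z <- which(!is.na(s) & s == 0)
  s[z] <- sign(slice4(v, 2))[z]
  z <- which(!is.na(s) & s == 0)
  s[z] <- sign(slice4(v, 3))[z]
  s[is.na(s) | s == 0] <- 1
  for (c_ in 1:3) v[, , , c_] <- slice4(v, c_) * s
  v
}

#' @export
print.orientation_field <- function(x, ...) {
  n <- sum(!is.na(slice4(x$vectors, 1)))
  cat(sprintf("<orientation_field> %d x %d x %d, %d defined vectors (axial)\n",
              x$dim[1], x$dim[2], x$dim[3], n))
  invisible(x)
}

#' @export
as_tibble.orientation_field <- function(x, ...) {
  def <- which(!is.na(slice4(x$vectors, 1)), arr.ind = TRUE)
  li <- linear_index(def, x$dim)
  n3 <- prod(x$dim)
  tibble(i = def[, 1], j = def[, 2], k = def[, 3],
         vx = x$vectors[li], vy = x$vectors[li + n3], vz = x$vectors[li + 2 * n3])
}

# Orientation vectors at an n x 3 matrix of voxel indices (rows may be NA).
field_vectors_at <- function(field, idx) {
  li <- linear_index(idx, field$dim)
  n3 <- prod(field$dim)
  cbind(field$vectors[li], field$vectors[li + n3], field$vectors[li + 2 * n3])
}

validate_geometry_pair <- function(geom, field) {
  stopifnot(inherits(geom, "voxel_geometry"))
  if (!is.null(field)) {
    stopifnot(inherits(field, "orientation_field"))
    if (!all(field$dim == geom$dim)) stop("geometry/field shape mismatch")
  }
  invisible(TRUE)
}
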