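#' Write a voxel geometry (and optional fibre field) to disk
#'
#' Two containers are supported:
#' * `"nifti"`: the mask is written as an unsigned 8-bit NIfTI volume at
#'   `<path>_mask.nii` and the orientation field, if present, as a 4-d
#'   double-precision volume (`x,y,z,component`) at `<path>_fibres.nii` with a
#'   matching header. Voxel spacing is stored in `pixdim`. Double storage
#'   makes the round trip bit-exact.
#' * `"rds"`: a single native archive `<path>.rds` holding mask, vectors,
#'   spacing and origin; bit-exact by construction.
#'
#' @param geom a [voxel_geometry()].
#' @param field an [orientation_field()] or `NULL` (mask-only file, usable by
#'   the fibre-less null model).
#' @param path output path stem (extensions are added).
#' @param format `"nifti"` or `"rds"`.
#' @return Invisibly, the character vector of files written.
#' @seealso [read_geometry()]
#' @export
write_geometry <- function(geom, field = NULL, path, format = c("nifti", "rds")) {
  format <- match.arg(format)
  validate_geometry_pair(geom, field)
  if (format == "rds") {
    f <- paste0(sub("\\.rds$", "", path), ".rds")
    saveRDS(list(mask = geom$mask, vectors = if (!is.null(field)) field$vectors,
                 spacing = geom$spacing, origin = geom$origin,
                 container = "fibrenet-geometry", version = 1L), f)
    return(invisible(f))
  }
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  fmask <- paste0(stem, "_mask.nii")
  pd <- rep(geom$spacing, 3)
  marr <- array(as.integer(geom$mask), geom$dim)
  attr(marr, "pixdim") <- pd
  RNifti::writeNifti(RNifti::asNifti(marr, datatype = "uint8"), fmask)
  files <- fmask
  if (!is.null(field)) {
    ffib <- paste0(stem, "_fibres.nii")
    vec <- field$vectors
    vec[is.na(vec)] <- 0 # NIfTI has no NA; zeros mark missing/outside
    attr(vec, "pixdim") <- pd
    RNifti::writeNifti(RNifti::asNifti(vec, datatype = "double"), ffib)
    files <- c(files, ffib)
  }
  invisible(files)
}

#' Read a voxel geometry (and fibre field if present)
#'
#' Counterpart of [write_geometry()]. Orientation vectors are renormalized to
#' unit length; vectors at unoccupied voxels are discarded; zero vectors at
#' occupied voxels are an error listing the offending voxel indices.
#'
#' @param path path stem or file written by [write_geometry()].
#' @param format `"nifti"` or `"rds"`.
#' @return A list with elements `geometry` ([voxel_geometry()]) and `field`
#'   ([orientation_field()] or `NULL` for mask-only files).
#' @export
read_geometry <- function(path, format = c("nifti", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    f <- if (file.exists(path)) path else paste0(path, ".rds")
    if (!file.exists(f)) stop("cannot read geometry: ", f)
    x <- readRDS(f)
    if (!identical(x$container, "fibrenet-geometry"))
      stop("not a fibrenet geometry archive: ", f)
    geom <- voxel_geometry(x$mask, spacing = x$spacing, origin = x$origin)
    field <- if (!is.null(x$vectors)) orientation_field(x$vectors, geom)
    return(list(geometry = geom, field = field))
  }
  stem <- sub("(_mask|_fibres)?\\.nii(\\.gz)?$", "", path)
  fmask <- paste0(stem, "_mask.nii")
  if (!file.exists(fmask)) stop("cannot read geometry: ", fmask)
  img <- RNifti::readNifti(fmask)
  spacing <- RNifti::pixdim(img)[1]
  geom <- voxel_geometry(array(as.logical(img > 0), dim(img)[1:3]),
                         spacing = spacing)
  ffib <- paste0(stem, "_fibres.nii")
  field <- NULL
  if (file.exists(ffib)) {
    vimg <- RNifti::readNifti(ffib)
    if (length(dim(vimg)) != 4L || !all(dim(vimg)[1:3] == geom$dim))
      stop("shape mismatch between mask and vector grids")
    vec <- array(as.numeric(vimg), dim(vimg))
    # zeros written for missing/outside voxels become NA before validation
    nrm <- sqrt(slice4(vec, 1)^2 + slice4(vec, 2)^2 + slice4(vec, 3)^2)
    zero_out <- !geom$mask & nrm < 1e-12
    for (c_ in 1:3) {
      sl <- slice4(vec, c_)
      sl[zero_out] <- NA_real_
      vec[, , , c_] <- sl
    }
    field <- orientation_field(vec, geom)
  }
  list(geometry = geom, field = field)
}

#' Coarse grain a geometry and its orientation field
#'
#' Aggregates `factor^3` blocks of voxels into one. An output voxel is
#' occupied iff at least half of its (in-grid) child voxels are occupied
#' (ties count as occupied), a conservative rule that preserves thin walls.
#' The output orientation is the principal eigenvector of the mean structure
#' tensor (outer product) of the child vectors — the standard sign-invariant
#' average for axial data: antiparallel children reinforce rather than
#' cancel. Voxel spacing is multiplied by `factor`.
#'
#' @param geom a [voxel_geometry()].
#' @param field an [orientation_field()] or `NULL`.
#' @param factor positive integer block size; `factor = 1` returns the inputs
#'   unchanged.
#' @return A list with elements `geometry` and `field` (or `NULL`).
#' @details If an occupied output voxel has no child vectors, its orientation
#'   is flagged missing (with a warning), never fabricated. A degenerate
#'   structure tensor (tied leading eigenvalues) resolves to the
#'   lexicographically smallest unit eigenvector, with a warning.
#' @export
coarse_grain_field <- function(geom, field = NULL, factor) {
  validate_geometry_pair(geom, field)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(list(geometry = geom, field = field))

  dims <- geom$dim
  odims <- as.integer(ceiling(dims / factor))

  block_sum <- function(arr) {
    # sum of a (padded-with-0) array over factor^3 blocks
    pad_dims <- odims * factor
    p <- array(0, pad_dims)
    p[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- arr
    # collapse each axis in turn
    dim(p) <- c(factor, pad_dims[1] / factor, pad_dims[2], pad_dims[3])
    p <- colSums(p)
    dim(p) <- c(odims[1], factor, pad_dims[2] / factor, pad_dims[3])
    p <- aperm(p, c(2, 1, 3, 4))
    p <- colSums(p)
    dim(p) <- c(odims[1], odims[2], factor, pad_dims[3] / factor)
    p <- aperm(p, c(3, 1, 2, 4))
    colSums(p)
  }

  occ_sum <- block_sum(geom$mask * 1)
  child_n <- block_sum(array(1, dims))
  omask <- 2 * occ_sum >= child_n # ties -> occupied
  ogeom <- voxel_geometry(omask, spacing = geom$spacing * factor,
                          origin = geom$origin)
  if (is.null(field)) return(list(geometry = ogeom, field = NULL))

  comp <- function(c_) { x <- slice4(field$vectors, c_); x[is.na(x)] <- 0; x }
  vx <- comp(1); vy <- comp(2); vz <- comp(3)
  has_v <- (vx^2 + vy^2 + vz^2) > 0.5
  cnt <- block_sum(has_v * 1)
  txx <- block_sum(vx * vx); txy <- block_sum(vx * vy); txz <- block_sum(vx * vz)
  tyy <- block_sum(vy * vy); tyz <- block_sum(vy * vz); tzz <- block_sum(vz * vz)

  ovec <- array(NA_real_, c(odims, 3))
  occ_idx <- which(omask & cnt > 0, arr.ind = TRUE)
  degen <- FALSE
  n3 <- prod(odims)
  for (r in seq_len(nrow(occ_idx))) {
    li <- linear_index(occ_idx[r, , drop = FALSE], odims)
    m <- cnt[li]
    T3 <- matrix(c(txx[li], txy[li], txz[li],
                   txy[li], tyy[li], tyz[li],
                   txz[li], tyz[li], tzz[li]), 3, 3) / m
    e <- eigen(T3, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (e$values[1] - e$values[2] < 1e-12) {
      degen <- TRUE
      # tie: lexicographically smallest unit eigenvector among the tied ones
      tied <- which(e$values[1] - e$values < 1e-12)
      cand <- lapply(tied, function(ix) {
        u <- e$vectors[, ix]
        s <- sign(u[match(TRUE, abs(u) > 0)]) # canonical axial sign
        u * if (is.na(s) || s == 0) 1 else s
      })
      ord <- order(vapply(cand, `[`, 0, 1), vapply(cand, `[`, 0, 2),
                   vapply(cand, `[`, 0, 3))
      v <- cand[[ord[1]]]
    }
    ovec[li] <- v[1]; ovec[li + n3] <- v[2]; ovec[li + 2 * n3] <- v[3]
  }
  if (degen) warning("degenerate structure tensor in some blocks; ",
                     "lexicographically smallest eigenvector chosen")
  missing_occ <- omask & cnt == 0
  if (any(missing_occ))
    warning(sum(missing_occ),
            " occupied output voxels have no child vectors; flagged missing")
  ofield <- orientation_field(ovec, ogeom)
  list(geometry = ogeom, field = ofield)
}
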