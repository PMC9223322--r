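# Internal helpers shared across modules.

# Derive a stream of child seeds from one master seed, reproducibly and
# independently of the caller's RNG state. Values stay below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Weighted quantile (inverted-CDF definition): smallest x with F(x) >= p.
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

# Map continuous positions (voxel units, voxel (i,j,k) spans
# [i-1,i) x [j-1,j) x [k-1,k)) to 1-based voxel indices.
position_to_voxel <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  floor(p) + 1L
}

# 3-d component slice of a 4-d vector array, robust to singleton dims.
slice4 <- function(v, c_) array(v[, , , c_], dim(v)[1:3])

voxel_centres <- function(idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  idx - 0.5
}

# Linear index into a 3-d array from an n x 3 index matrix.
linear_index <- function(idx, dims) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  (idx[, 1] - 1L) + dims[1] * ((idx[, 2] - 1L) + dims[2] * (idx[, 3] - 1L)) + 1L
}

in_grid <- function(idx, dims) {
  idx[, 1] >= 1L & idx[, 1] <= dims[1] &
    idx[, 2] >= 1L & idx[, 2] <= dims[2] &
    idx[, 3] >= 1L & idx[, 3] <= dims[3]
}
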