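#' Specification of a synthetic geometry fixture
#'
#' Fixtures emulate the structural features of atrial tissue that drive
#' micro-reentry risk: thin convex walls (slab), thickness gradients (wedge),
#' pectinate-muscle-like ridges (ridge), pulmonary-vein-like tubes (sleeve),
#' local fibre disarray patches and small structural holes. They let every
#' downstream stage run and be tested without imaging data.
#'
#' @param kind one of `"slab"`, `"wedge"`, `"ridge"`, `"sleeve"`.
#' @param dims grid dimensions in voxels, length 3.
#' @param thickness plate thickness in voxels; for `"wedge"`, length 2
#'   `c(thin, thick)` giving a linear thickness ramp along x.
#' @param fibre_angle in-plane fibre angle in radians (0 = along x).
#' @param radius ridge (solid) or sleeve (outer) radius in voxels.
#' @param inner_radius sleeve lumen radius in voxels (`sleeve` only).
#' @param tube_length sleeve tube length in voxels above the plate.
#' @param disarray list of disarray regions, each
#'   `list(box = rbind(lo, hi), kappa = k, corr = l)`: within the inclusive
#'   voxel-index box, fibre vectors are redrawn from a von Mises-Fisher
#'   distribution about the local base direction with concentration `kappa`
#'   (> 0; `Inf` = unperturbed). `corr` (voxels, default 3) is the spatial
#'   correlation length of the perturbation: one draw is shared by each
#'   `corr`-voxel block, mimicking the patch-wise coherence of real fibre
#'   disarray (independent per-voxel directions would be untraceable by any
#'   streamline method).
#' @param holes list of spherical holes, each `list(centre = c(x,y,z),
#'   radius = r)` in voxel units; carved out of the mask.
#' @param seed RNG seed; the fixture is deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("slab", "wedge", "ridge", "sleeve"),
                         dims = c(40, 30, 4), thickness = NULL,
                         fibre_angle = 0, radius = 4, inner_radius = 3,
                         tube_length = 12, disarray = list(), holes = list(),
                         seed = 1L) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  thickness <- thickness %||% switch(kind, wedge = c(2, min(14, dims[3])),
                                     dims[3])
  if (kind == "wedge") {
    if (length(thickness) != 2L) stop("wedge `thickness` must be c(thin, thick)")
  } else if (length(thickness) != 1L) stop("`thickness` must be a scalar")
  if (any(thickness > dims[3]) || any(thickness < 1))
    stop("`thickness` must lie in [1, dims[3]]")
  for (d in disarray) {
    if (is.null(d$box) || is.null(d$kappa) || d$kappa <= 0)
      stop("each disarray region needs a `box` and `kappa` > 0")
  }
  for (h in holes) {
    if (is.null(h$centre) || is.null(h$radius) || h$radius < 0)
      stop("each hole needs a `centre` and `radius` >= 0")
  }
  structure(list(kind = kind, dims = dims, thickness = thickness,
                 fibre_angle = fibre_angle, radius = radius,
                 inner_radius = inner_radius, tube_length = tube_length,
                 disarray = disarray, holes = holes, seed = as.integer(seed)),
            class = "fixture_spec")
}

# von Mises-Fisher sample of n unit vectors about unit direction mu.
rvmf <- function(n, mu, kappa) {
  if (is.infinite(kappa)) return(matrix(mu, n, 3, byrow = TRUE))
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  ang <- runif(n, 0, 2 * pi)
  # orthonormal basis perpendicular to mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- ref - sum(ref * mu) * mu
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(mu[2] * b1[3] - mu[3] * b1[2],
          mu[3] * b1[1] - mu[1] * b1[3],
          mu[1] * b1[2] - mu[2] * b1[1])
  s <- sqrt(pmax(0, 1 - w^2))
  outer(w, mu) + outer(s * cos(ang), b1) + outer(s * sin(ang), b2)
}

#' Generate a synthetic geometry and fibre field
#'
#' Deterministic for a fixed spec (including its seed). Slabs are rectangular
#' plates with a uniform in-plane fibre angle; wedges ramp linearly from thin
#' to thick along x; ridges attach a half-cylinder (fibres running along the
#' ridge axis) to a plate; sleeves join a hollow vertical tube with
#' circumferential fibres to a plate. Disarray regions redraw vectors from a
#' von Mises-Fisher distribution about the base direction; holes carve
#' spheres out of the mask.
#'
#' @param spec a [fixture_spec()].
#' @return A list with elements `geometry` and `field`.
#' @examples
#' fx <- make_fixture(fixture_spec("slab", dims = c(40, 30, 4)))
#' n_occupied(fx$geometry) # 4800
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, make_fixture_impl(spec))
}

make_fixture_impl <- function(spec) {
  d <- spec$dims
  mask <- array(FALSE, d)
  vec <- array(NA_real_, c(d, 3))
  n3 <- prod(d)
  base_dir <- c(cos(spec$fibre_angle), sin(spec$fibre_angle), 0)

  set_plate <- function(th_per_x) {
    for (x in seq_len(d[1])) {
      t_ <- th_per_x[x]
      if (t_ >= 1) mask[x, , seq_len(t_)] <<- TRUE
    }
  }
  thin1 <- FALSE # is the plate 1 voxel thick anywhere (tangency constraint)

  if (spec$kind == "slab") {
    set_plate(rep(spec$thickness, d[1]))
    thin1 <- spec$thickness == 1
  } else if (spec$kind == "wedge") {
    th <- round(seq(spec$thickness[1], spec$thickness[2], length.out = d[1]))
    set_plate(th)
    thin1 <- any(th == 1)
  } else if (spec$kind == "ridge") {
    set_plate(rep(spec$thickness, d[1]))
    yc <- d[2] / 2 + 0.5
    zb <- spec$thickness # ridge sits on top of the plate
    for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (z > zb && (y - yc)^2 + (z - zb - 0.5)^2 <= spec$radius^2)
        mask[, y, z] <- TRUE
    }
  } else if (spec$kind == "sleeve") {
    set_plate(rep(spec$thickness, d[1]))
    xc <- d[1] / 2 + 0.5; yc <- d[2] / 2 + 0.5
    ztop <- min(d[3], spec$thickness + spec$tube_length)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
      r2 <- (x - xc)^2 + (y - yc)^2
      if (r2 <= spec$radius^2) {
        if (r2 >= spec$inner_radius^2) {
          mask[x, y, (spec$thickness + 1):ztop] <- TRUE # tube wall
        } else if (spec$thickness >= 1) {
          mask[x, y, seq_len(spec$thickness)] <- FALSE # ostium through plate
        }
      }
    }
  }

  # base fibre directions
  occ <- which(mask, arr.ind = TRUE)
  li <- linear_index(occ, d)
  vx <- rep(base_dir[1], nrow(occ)); vy <- rep(base_dir[2], nrow(occ))
  vz <- rep(0, nrow(occ))
  if (spec$kind == "ridge") {
    on_ridge <- occ[, 3] > spec$thickness
    vx[on_ridge] <- 1; vy[on_ridge] <- 0 # along the ridge axis
  } else if (spec$kind == "sleeve") {
    xc <- d[1] / 2 + 0.5; yc <- d[2] / 2 + 0.5
    on_tube <- occ[, 3] > spec$thickness
    cx <- occ[on_tube, 1] - 0.5 - (xc - 0.5); cy <- occ[on_tube, 2] - 0.5 - (yc - 0.5)
    nn <- sqrt(cx^2 + cy^2); nn[nn < 1e-12] <- 1
    vx[on_tube] <- -cy / nn; vy[on_tube] <- cx / nn # circumferential
  }
  vec[li] <- vx; vec[li + n3] <- vy; vec[li + 2 * n3] <- vz

  # disarray patches: vMF perturbation about the local base direction, one
  # draw per corr-voxel block (spatially coherent misalignment)
  for (reg in spec$disarray) {
    lo <- reg$box[1, ]; hi <- reg$box[2, ]
    corr <- max(1L, as.integer(reg$corr %||% 3L))
    inside <- occ[, 1] >= lo[1] & occ[, 1] <= hi[1] &
      occ[, 2] >= lo[2] & occ[, 2] <= hi[2] &
      occ[, 3] >= lo[3] & occ[, 3] <= hi[3]
    ids <- which(inside)
    if (length(ids) == 0L || is.infinite(reg$kappa)) next
    block <- cbind((occ[ids, 1] - lo[1]) %/% corr,
                   (occ[ids, 2] - lo[2]) %/% corr,
                   (occ[ids, 3] - lo[3]) %/% corr)
    bkey <- paste(block[, 1], block[, 2], block[, 3])
    for (bk in unique(bkey)) {
      members <- ids[bkey == bk]
      mu <- c(vec[li[members[1]]], vec[li[members[1]] + n3],
              vec[li[members[1]] + 2 * n3])
      s <- rvmf(1, mu, reg$kappa)
      if (thin1) { s[3] <- 0; s <- s / sqrt(sum(s^2)) } # keep tangent to plate
      vec[li[members]] <- s[1]; vec[li[members] + n3] <- s[2]
      vec[li[members] + 2 * n3] <- s[3]
    }
  }

  # holes: spheres removed from the mask (distance between voxel centres)
  for (h in spec$holes) {
    ctr <- voxel_centres(matrix(h$centre, 1))
    dd <- sqrt((occ[, 1] - 0.5 - ctr[1])^2 + (occ[, 2] - 0.5 - ctr[2])^2 +
                 (occ[, 3] - 0.5 - ctr[3])^2)
    cut <- dd <= h$radius
    if (any(cut)) {
      mask[li[cut]] <- FALSE
      vec[li[cut]] <- NA_real_; vec[li[cut] + n3] <- NA_real_
      vec[li[cut] + 2 * n3] <- NA_real_
    }
  }

  geom <- voxel_geometry(mask)
  field <- orientation_field(vec, geom)
  list(geometry = geom, field = field)
}

#' Canonical fixture suite
#'
#' The named set of synthetic geometries used throughout the tests and the
#' acceptance analyses: thin and thick slabs, a wedge (thickness ramp for
#' wall-thickness bias analyses), a ridge on a plate, a pulmonary-vein-like
#' sleeve, a slab with a fibre-disarray patch (plus a mirror-image aligned
#' control box), and a slab with structural holes.
#'
#' @param seed RNG seed forwarded to every member spec.
#' @return Named list of `fixture_spec` objects (pass each to
#'   [make_fixture()]).
#' @details The disarray slab carries attributes `patch_box` and
#'   `control_box`: two congruent boxes mirror-symmetric about the slab
#'   midplane in x, so that geometric boundary effects cancel when comparing
#'   substrate density inside the disarray patch against aligned tissue.
#' @export
fixture_suite <- function(seed = 1L) {
  patch <- rbind(c(8, 10, 1), c(19, 21, 4))
  control <- rbind(c(22, 10, 1), c(33, 21, 4))
  dis <- fixture_spec("slab", dims = c(40, 30, 4), thickness = 4,
                      disarray = list(list(box = patch, kappa = 2)),
                      seed = seed)
  attr(dis, "patch_box") <- patch
  attr(dis, "control_box") <- control
  list(
    thin_slab = fixture_spec("slab", dims = c(40, 30, 4), thickness = 4, seed = seed),
    thick_slab = fixture_spec("slab", dims = c(40, 30, 12), thickness = 12, seed = seed),
    wedge = fixture_spec("wedge", dims = c(60, 40, 16), thickness = c(2, 14), seed = seed),
    ridge = fixture_spec("ridge", dims = c(40, 30, 10), thickness = 3, radius = 4, seed = seed),
    sleeve = fixture_spec("sleeve", dims = c(30, 30, 18), thickness = 3,
                          radius = 5, inner_radius = 3, tube_length = 12, seed = seed),
    disarray_slab = dis,
    holey_slab = fixture_spec("slab", dims = c(40, 30, 4), thickness = 4,
                              holes = list(list(centre = c(12, 10, 2), radius = 2.5),
                                           list(centre = c(28, 20, 2), radius = 2.5)),
                              seed = seed)
  )
}
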