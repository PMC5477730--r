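#' Boolean voxel mask of a structure
#'
#' Voxel realization of a delineated structure on a regular grid. The
#' package uses the voxel-centre convention throughout: a voxel belongs to
#' a structure iff its centre lies inside the continuous set. Voxel `(i,
#' j, k)` (1-based) has its centre at `origin + (c(i, j, k) - 1) *
#' spacing`.
#'
#' @param origin 3-vector, position of the first voxel centre (mm).
#' @param spacing 3-vector, per-axis voxel size (mm), all positive.
#' @param occupancy 3D logical array.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(origin, spacing, occupancy) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L) {
    stop("origin and spacing must be length-3")
  }
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L) {
    stop("occupancy must be a 3D array")
  }
  storage.mode(occupancy) <- "logical"
  structure(list(origin = origin, spacing = spacing,
                 shape = dim(occupancy), occupancy = occupancy),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  occupied: %d voxels = %.2f cm^3\n",
              sum(x$occupancy), mask_volume(x) / 1000))
  invisible(x)
}

#' Occupied volume of a mask
#' @param mask a [structure_mask()].
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  sum(mask$occupancy) * prod(mask$spacing)
}

# per-axis voxel-centre coordinates
.axis_coords <- function(mask) {
  lapply(1:3, function(d) mask$origin[d] + (seq_len(mask$shape[d]) - 1) * mask$spacing[d])
}

.same_grid <- function(a, b, tol = 1e-6) {
  all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(a$shape == b$shape)
}

.check_grid <- function(a, b, what) {
  if (!.same_grid(a, b)) {
    stop(sprintf("%s: grid geometry mismatch (origin/spacing/shape must agree)", what))
  }
}

#' Rasterize a closed mesh onto a voxel grid
#'
#' Marks every voxel whose centre lies strictly inside the surface, by
#' even-odd in-polygon tests against the mesh cross-section on each axial
#' slice of the grid.
#'
#' @param mesh a closed [triangular_mesh()].
#' @param origin,spacing,shape target grid geometry (see
#'   [structure_mask()]).
#' @param like optionally a `structure_mask` or `dose_grid` whose geometry
#'   is reused instead of `origin`/`spacing`/`shape`.
#' @return a [structure_mask()].
#' @export
rasterize <- function(mesh, origin = NULL, spacing = NULL, shape = NULL,
                      like = NULL) {
  stopifnot(inherits(mesh, "triangular_mesh"))
  if (mesh_open_edges(mesh) > 0L) {
    stop("rasterize: mesh is not closed")
  }
  if (!is.null(like)) {
    origin <- like$origin; spacing <- like$spacing; shape <- like$shape
  }
  shape <- as.integer(shape)
  occ <- array(FALSE, shape)
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  px <- rep(xs, times = shape[2])
  py <- rep(ys, each = shape[1])
  zr <- range(mesh$vertices[, 3L])
  for (k in seq_len(shape[3])) {
    if (zs[k] <= zr[1] || zs[k] >= zr[2]) next
    contours <- slice_mesh(mesh, zs[k])
    if (!length(contours)) next
    inside <- rep(FALSE, length(px))
    for (ct in contours) {
      p <- ct$points
      n <- nrow(p) - 1L
      for (j in seq_len(n)) {   # even-odd ray cast, toggling per crossing
        y1 <- p[j, 2L]; y2 <- p[j + 1L, 2L]
        if (y1 == y2) next
        x1 <- p[j, 1L]; x2 <- p[j + 1L, 1L]
        crosses <- (y1 > py) != (y2 > py)
        xi <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        inside <- xor(inside, crosses & px < xi)
      }
    }
    occ[, , k] <- inside
  }
  structure_mask(origin, spacing, occ)
}

#' Extract the boundary isosurface of a voxel mask as a closed mesh
#'
#' Emits the voxel-boundary isosurface: every face between an occupied and
#' an unoccupied voxel becomes an outward-oriented quad (two triangles) on
#' the voxel-corner lattice. The resulting mesh is closed and consistently
#' wound, and its signed-tetrahedron volume equals the voxel-count volume
#' of the mask exactly.
#'
#' @param mask a non-empty [structure_mask()].
#' @return a [triangular_mesh()].
#' @export
mask_to_mesh <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  occ <- mask$occupancy
  if (!any(occ)) stop("mask_to_mesh: empty mask")
  sh <- mask$shape
  pad <- array(FALSE, sh + 2L)
  pad[2:(sh[1] + 1L), 2:(sh[2] + 1L), 2:(sh[3] + 1L)] <- occ

  # corner lattice: corner (ci,cj,ck), 0-based 0..sh, position
  # origin + (c(ci,cj,ck) - 0.5) * spacing
  cid <- function(ci, cj, ck) 1 + ci + (sh[1] + 1) * (cj + (sh[2] + 1) * ck)

  quads <- list()
  # For axis d and sign s, boundary faces where pad is TRUE and the
  # neighbour along (d, s) is FALSE.
  shift_idx <- function(arr, d, s) {
    i <- 2:(sh[1] + 1L); j <- 2:(sh[2] + 1L); k <- 2:(sh[3] + 1L)
    if (d == 1L) i <- i + s else if (d == 2L) j <- j + s else k <- k + s
    arr[i, j, k, drop = FALSE]
  }
  for (d in 1:3) for (s in c(1L, -1L)) {
    b <- occ & !shift_idx(pad, d, s)
    w <- which(b, arr.ind = TRUE)
    if (!nrow(w)) next
    i0 <- w[, 1L] - 1L; j0 <- w[, 2L] - 1L; k0 <- w[, 3L] - 1L
    # corner offset of the face plane along axis d
    od <- ifelse(s == 1L, 1L, 0L)
    if (d == 1L) {
      ci <- i0 + od
      # +x: CCW in (y,z); -x reversed
      q <- cbind(cid(ci, j0,     k0),     cid(ci, j0 + 1, k0),
                 cid(ci, j0 + 1, k0 + 1), cid(ci, j0,     k0 + 1))
    } else if (d == 2L) {
      cj <- j0 + od
      # +y: CCW in (z,x)
      q <- cbind(cid(i0,     cj, k0),     cid(i0,     cj, k0 + 1),
                 cid(i0 + 1, cj, k0 + 1), cid(i0 + 1, cj, k0))
    } else {
      ck <- k0 + od
      # +z: CCW in (x,y)
      q <- cbind(cid(i0,     j0, ck), cid(i0 + 1, j0,     ck),
                 cid(i0 + 1, j0 + 1, ck), cid(i0, j0 + 1, ck))
    }
    if (s == -1L) q <- q[, 4:1, drop = FALSE]
    quads[[length(quads) + 1L]] <- q
  }
  q <- do.call(rbind, quads)
  tris <- rbind(q[, c(1L, 2L, 3L), drop = FALSE], q[, c(1L, 3L, 4L), drop = FALSE])

  used <- sort(unique(as.vector(tris)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  tris[] <- remap[tris]
  u0 <- used - 1L
  ci <- u0 %% (sh[1] + 1L)
  cj <- (u0 %/% (sh[1] + 1L)) %% (sh[2] + 1L)
  ck <- u0 %/% ((sh[1] + 1L) * (sh[2] + 1L))
  verts <- cbind(mask$origin[1] + (ci - 0.5) * mask$spacing[1],
                 mask$origin[2] + (cj - 0.5) * mask$spacing[2],
                 mask$origin[3] + (ck - 0.5) * mask$spacing[3])
  triangular_mesh(verts, tris, normalize = FALSE)
}

#' Isotropic margin expansion of a voxel mask
#'
#' Occupies every voxel centre within Euclidean distance `margin` of the
#' occupied set, using an exact anisotropic-spacing Euclidean distance
#' transform (not an iterated structuring-element dilation, which is
#' inaccurate for large margins on anisotropic grids). The expansion is
#' clipped at the grid bounds, so grids must be sized with headroom.
#'
#' @param mask a [structure_mask()].
#' @param margin expansion margin (mm), `>= 0`. Contraction is a separate
#'   concern and not supported.
#' @return a [structure_mask()] on the same grid.
#' @export
expand_isotropic <- function(mask, margin) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.finite(margin) || margin < 0) {
    stop("expand_isotropic: margin must be >= 0")
  }
  if (margin == 0 || !any(mask$occupancy)) return(mask)
  d2 <- .edt_squared(as.logical(mask$occupancy), mask$shape, mask$spacing)
  occ <- array(d2 <= margin^2 + 1e-9, mask$shape)
  structure_mask(mask$origin, mask$spacing, occ)
}

#' Anatomical barrier set
#'
#' Bundles the air, bone and generic anatomical-boundary masks used to
#' crop expanded target volumes. All three must share one grid.
#'
#' @param air,bone,anatomical [structure_mask()] objects on a common grid.
#' @return an object of class `barrier_set`.
#' @export
barrier_set <- function(air, bone, anatomical) {
  .check_grid(air, bone, "barrier_set")
  .check_grid(air, anatomical, "barrier_set")
  structure(list(air = air, bone = bone, anatomical = anatomical),
            class = "barrier_set")
}

#' Crop a mask at anatomical barriers
#'
#' Removes every voxel lying in the air, bone or anatomical-boundary
#' barrier: `result = mask AND NOT (air OR bone OR anatomical)`.
#'
#' @param mask a [structure_mask()].
#' @param barriers a [barrier_set()] on the same grid.
#' @return cropped [structure_mask()].
#' @export
crop_to_barriers <- function(mask, barriers) {
  stopifnot(inherits(barriers, "barrier_set"))
  .check_grid(mask, barriers$air, "crop_to_barriers")
  occ <- mask$occupancy & !(barriers$air$occupancy |
                            barriers$bone$occupancy |
                            barriers$anatomical$occupancy)
  structure_mask(mask$origin, mask$spacing, occ)
}

#' Boolean operations on masks
#'
#' `mask_subtract(a, b)` is `a AND NOT b` (e.g. `CTV_delta = CTV_L minus
#' CTV_S`); `mask_union` and `mask_intersect` are the corresponding set
#' operations. All require identical grid geometry.
#'
#' @param a,b [structure_mask()] objects on the same grid.
#' @return a [structure_mask()].
#' @export
mask_subtract <- function(a, b) {
  .check_grid(a, b, "mask_subtract")
  structure_mask(a$origin, a$spacing, a$occupancy & !b$occupancy)
}

#' @rdname mask_subtract
#' @export
mask_union <- function(a, b) {
  .check_grid(a, b, "mask_union")
  structure_mask(a$origin, a$spacing, a$occupancy | b$occupancy)
}

#' @rdname mask_subtract
#' @export
mask_intersect <- function(a, b) {
  .check_grid(a, b, "mask_intersect")
  structure_mask(a$origin, a$spacing, a$occupancy & b$occupancy)
}

#' Build a clinical target volume from a gross tumour volume
#'
#' The GTV-to-CTV chain: isotropic margin expansion first, barrier
#' cropping second (the composition order is fixed; cropping before
#' expanding would let the margin re-enter barriers).
#'
#' @param gtv the gross tumour volume mask.
#' @param margin isotropic CTV margin (mm); the clinical default used
#'   throughout this package is 8 mm.
#' @param barriers a [barrier_set()].
#' @return the CTV as a [structure_mask()]; never occupies a barrier
#'   voxel.
#' @export
build_ctv <- function(gtv, margin = 8, barriers) {
  crop_to_barriers(expand_isotropic(gtv, margin), barriers)
}

#' CT display window preset
#'
#' Hounsfield-unit range of a CT display preset. The lung window used for
#' delineation against air spans `[-1000, 0]` HU.
#'
#' @param hu_min,hu_max window bounds in HU, `hu_min < hu_max`.
#' @return an object of class `window_preset`.
#' @export
window_preset <- function(hu_min = -1000, hu_max = 0) {
  if (!(hu_min < hu_max)) stop("window_preset: hu_min must be < hu_max")
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "window_preset")
}
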