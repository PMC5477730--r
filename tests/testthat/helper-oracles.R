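# Independent brute-force oracles. These deliberately re-derive results
# with different algorithms than the package (no spatial acceleration, no
# distance transform) so agreement is meaningful.

# point-to-triangle distance via constrained projection: solve the
# unconstrained least squares in the triangle plane, clamp to the three
# edges when the barycentric solution leaves the triangle.
oracle_point_tri_dist <- function(p, a, b, c) {
  e1 <- b - a; e2 <- c - a; ap <- p - a
  g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
  r1 <- sum(e1 * ap); r2 <- sum(e2 * ap)
  det <- g11 * g22 - g12 * g12
  seg <- function(q, s, t) {
    st <- t - s
    h <- sum(st * st)
    tt <- if (h <= 0) 0 else max(0, min(1, sum((q - s) * st) / h))
    sqrt(sum((q - (s + tt * st))^2))
  }
  if (det > 1e-300) {
    u <- (g22 * r1 - g12 * r2) / det
    w <- (g11 * r2 - g12 * r1) / det
    if (u >= 0 && w >= 0 && u + w <= 1) {
      return(sqrt(sum((p - (a + u * e1 + w * e2))^2)))
    }
  }
  min(seg(p, a, b), seg(p, b, c), seg(p, a, c))
}

# directed max-min distance from sampled points to the full surface,
# scanning all triangles for every point
oracle_directed_hd <- function(pts, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  worst <- 0
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    best <- Inf
    for (j in seq_len(nrow(f))) {
      d <- oracle_point_tri_dist(p, v[f[j, 1], ], v[f[j, 2], ], v[f[j, 3], ])
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  worst
}

# exhaustive isotropic expansion: voxel-wise min distance to every
# occupied voxel centre
oracle_expand <- function(mask, margin) {
  occ <- mask$occupancy
  idx <- which(occ, arr.ind = TRUE)
  src <- cbind((idx[, 1] - 1) * mask$spacing[1],
               (idx[, 2] - 1) * mask$spacing[2],
               (idx[, 3] - 1) * mask$spacing[3])
  out <- array(FALSE, dim(occ))
  all_idx <- which(array(TRUE, dim(occ)), arr.ind = TRUE)
  pts <- cbind((all_idx[, 1] - 1) * mask$spacing[1],
               (all_idx[, 2] - 1) * mask$spacing[2],
               (all_idx[, 3] - 1) * mask$spacing[3])
  for (i in seq_len(nrow(pts))) {
    d2 <- (src[, 1] - pts[i, 1])^2 + (src[, 2] - pts[i, 2])^2 +
      (src[, 3] - pts[i, 3])^2
    out[all_idx[i, 1], all_idx[i, 2], all_idx[i, 3]] <-
      min(d2) <= margin^2 + 1e-9
  }
  structure_mask(mask$origin, mask$spacing, out)
}

# analytic ball mask on a unit-offset grid: centres within radius of ctr
ball_mask <- function(radius, spacing = c(1, 1, 1), half_extent = 21,
                      ctr = c(0, 0, 0)) {
  n <- 2L * half_extent + 1L
  xs <- (-half_extent:half_extent) * spacing[1]
  ys <- (-half_extent:half_extent) * spacing[2]
  zs <- (-half_extent:half_extent) * spacing[3]
  occ <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    occ[, , k] <- outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+") +
      (zs[k] - ctr[3])^2 <= radius^2
  }
  structure_mask(c(xs[1], ys[1], zs[1]), spacing, occ)
}

# random blob mask for property tests (fixed seed supplied by caller)
random_mask <- function(shape = c(12, 12, 8), spacing = c(1, 1.3, 2.1),
                        p = 0.08) {
  occ <- array(runif(prod(shape)) < p, shape)
  occ[1, 1, 1] <- TRUE
  structure_mask(c(0, 0, 0), spacing, occ)
}

uniform_dose <- function(gy, shape = c(6, 6, 4), spacing = c(1, 1, 1),
                         prescription = 70) {
  dose_grid(c(0, 0, 0), spacing, array(gy, shape), prescription)
}

full_mask <- function(shape = c(6, 6, 4), spacing = c(1, 1, 1)) {
  structure_mask(c(0, 0, 0), spacing, array(TRUE, shape))
}
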