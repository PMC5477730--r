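#' Intersect a mesh with an axial plane
#'
#' Returns the closed intersection polylines of the mesh with the plane at
#' height `z`. If `z` coincides exactly with mesh vertices the plane is
#' nudged by a micrometre to keep the intersection generic; axial slice
#' positions used elsewhere in the package fall between voxel-corner
#' lattices, so the nudge only matters for hand-built meshes.
#'
#' @param mesh a [triangular_mesh()].
#' @param z axial plane position (mm).
#' @return a list of planar contours, each a list with elements `z` and
#'   `points` (closed 2-column matrix: first row repeated last).
#' @export
slice_mesh <- function(mesh, z) {
  stopifnot(inherits(mesh, "triangular_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  if (any(abs(v[, 3L] - z) < 1e-9)) z <- z + 1e-6
  s <- matrix(v[f, 3L], ncol = 3L) - z
  hit <- which(apply(s > 0, 1L, any) & apply(s < 0, 1L, any))
  if (!length(hit)) return(list())

  seg_a <- matrix(NA_real_, length(hit), 2L)
  seg_b <- matrix(NA_real_, length(hit), 2L)
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  filled <- integer(length(hit))  # how many endpoints found per face
  for (ep in edge_pairs) {
    i1 <- f[hit, ep[1L]]; i2 <- f[hit, ep[2L]]
    s1 <- s[hit, ep[1L]]; s2 <- s[hit, ep[2L]]
    cross <- s1 * s2 < 0
    t <- s1 / (s1 - s2)
    px <- v[i1, 1L] + t * (v[i2, 1L] - v[i1, 1L])
    py <- v[i1, 2L] + t * (v[i2, 2L] - v[i1, 2L])
    first <- cross & filled == 0L
    second <- cross & filled == 1L
    seg_a[first, ] <- cbind(px[first], py[first])
    seg_b[second, ] <- cbind(px[second], py[second])
    filled <- filled + as.integer(cross)
  }
  ok <- filled == 2L
  seg_a <- seg_a[ok, , drop = FALSE]
  seg_b <- seg_b[ok, , drop = FALSE]
  if (!nrow(seg_a)) return(list())

  # chain segments into closed loops by matching rounded endpoints
  keyof <- function(p) paste(round(p[, 1L], 6L), round(p[, 2L], 6L))
  ka <- keyof(seg_a); kb <- keyof(seg_b)
  nseg <- length(ka)
  ends <- data.frame(key = c(ka, kb), seg = rep(seq_len(nseg), 2L),
                     side = rep(c(1L, 2L), each = nseg),
                     stringsAsFactors = FALSE)
  bykey <- split(seq_len(nrow(ends)), ends$key)
  used <- logical(nseg)
  contours <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    loop_x <- numeric(0); loop_y <- numeric(0)
    cur <- start; curkey <- ka[start]
    repeat {
      used[cur] <- TRUE
      # append the endpoint we arrive from, walk to the other endpoint
      if (curkey == ka[cur]) {
        loop_x <- c(loop_x, seg_a[cur, 1L]); loop_y <- c(loop_y, seg_a[cur, 2L])
        nextkey <- kb[cur]
      } else {
        loop_x <- c(loop_x, seg_b[cur, 1L]); loop_y <- c(loop_y, seg_b[cur, 2L])
        nextkey <- ka[cur]
      }
      cand <- ends$seg[bykey[[nextkey]]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1L]; curkey <- nextkey
    }
    if (length(loop_x) >= 3L) {
      pts <- cbind(loop_x, loop_y)
      pts <- rbind(pts, pts[1L, ])
      dimnames(pts) <- NULL
      contours[[length(contours) + 1L]] <- list(z = z, points = pts)
    }
  }
  contours
}

# densify a closed polyline: vertices plus points every `step` mm on edges
.contour_samples <- function(contours, step = 0.5) {
  out <- lapply(contours, function(ct) {
    p <- ct$points
    n <- nrow(p) - 1L
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      k <- max(1L, ceiling(len / step))
      t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
      pieces[[i]] <- cbind(a[1L] + t * (b[1L] - a[1L]),
                           a[2L] + t * (b[2L] - a[2L]))
    }
    do.call(rbind, pieces)
  })
  do.call(rbind, out)
}

# min distance from each 2D point to any segment of the contour set
.dist_to_contours <- function(pts, contours) {
  best <- rep(Inf, nrow(pts))
  for (ct in contours) {
    p <- ct$points
    a <- p[-nrow(p), , drop = FALSE]
    b <- p[-1L, , drop = FALSE]
    ab <- b - a
    len2 <- pmax(rowSums(ab^2), 1e-300)
    for (j in seq_len(nrow(a))) {
      dx <- pts[, 1L] - a[j, 1L]
      dy <- pts[, 2L] - a[j, 2L]
      t <- pmin(1, pmax(0, (dx * ab[j, 1L] + dy * ab[j, 2L]) / len2[j]))
      d2 <- (dx - t * ab[j, 1L])^2 + (dy - t * ab[j, 2L])^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

# symmetric 2D Hausdorff distance between two contour sets on one slice
.hd2d_slice <- function(ca, cb, step = 0.5) {
  pa <- .contour_samples(ca, step)
  pb <- .contour_samples(cb, step)
  max(max(.dist_to_contours(pa, cb)), max(.dist_to_contours(pb, ca)))
}

#' Slice-wise 2D Hausdorff distance between two meshes
#'
#' Both meshes are cut into axial contours on a common stack of slice
#' positions spanning their joint z-extent. On every slice where both
#' structures have contours, the symmetric 2D Hausdorff distance between
#' the contour sets is computed from densified polyline samples against
#' exact point-to-segment distances. The per-structure summary is the
#' maximum over shared slices (the most conservative reduction); the full
#' per-slice map is returned so other reductions (median, ...) can be
#' recomputed. Slices where only one structure exists are counted as
#' `unmatched_slices` and excluded: a 2D distance is undefined there.
#'
#' @param a,b [triangular_mesh()] objects.
#' @param slice_spacing distance between axial slices (mm).
#' @param densify_step polyline sampling step (mm).
#' @return list with `summary` (mm), `per_slice` (named vector, names are
#'   slice z positions), and `unmatched_slices` (integer).
#' @export
hausdorff_2d_axial <- function(a, b, slice_spacing = 2, densify_step = 0.5) {
  stopifnot(inherits(a, "triangular_mesh"), inherits(b, "triangular_mesh"))
  za <- range(a$vertices[, 3L]); zb <- range(b$vertices[, 3L])
  if (za[1L] > zb[2L] || zb[1L] > za[2L]) {
    stop("hausdorff_2d_axial: meshes do not overlap in z")
  }
  zlo <- min(za[1L], zb[1L]); zhi <- max(za[2L], zb[2L])
  zs <- seq(zlo + slice_spacing / 2, zhi, by = slice_spacing)
  per <- numeric(0)
  unmatched <- 0L
  for (z in zs) {
    ca <- slice_mesh(a, z)
    cb <- slice_mesh(b, z)
    if (length(ca) && length(cb)) {
      per[as.character(z)] <- .hd2d_slice(ca, cb, densify_step)
    } else if (length(ca) || length(cb)) {
      unmatched <- unmatched + 1L
    }
  }
  if (!length(per)) stop("hausdorff_2d_axial: no shared slices")
  list(summary = max(per), per_slice = per, unmatched_slices = unmatched)
}
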