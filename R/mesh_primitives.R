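#' Analytic mesh primitives
#'
#' Small generators for closed, consistently wound test meshes: an
#' axis-aligned box, a subdivided icosphere, a capped cylinder with axis
#' along z, and a torus with axis along z. They back the analytic geometry
#' checks (exact box volume, `4/3*pi*r^3` spheres, cylinder cross sections,
#' torus topology) used throughout the test-suite and the examples.
#'
#' @param lo,hi opposite corners of the box (mm).
#' @return a [triangular_mesh()].
#' @name mesh_primitives
NULL

#' @rdname mesh_primitives
#' @export
mesh_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = hi (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = lo (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = hi (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = lo (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = hi (+x)
  triangular_mesh(v, f, normalize = TRUE)
}

#' @rdname mesh_primitives
#' @param radius sphere/cylinder/tube radius (mm).
#' @param center 3-vector, mm.
#' @param subdivisions icosphere subdivision level; level s gives
#'   `20 * 4^s` faces. Level 4 keeps the enclosed volume within 0.1% of
#'   `4/3*pi*r^3`.
#' @export
mesh_icosphere <- function(radius = 10, center = c(0, 0, 0), subdivisions = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    # midpoint of each undirected edge, deduplicated
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ukey <- unique(key)
    mididx <- match(key, ukey) + nrow(v)
    ue <- e[match(ukey, key), , drop = FALSE]
    mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  triangular_mesh(v, f, normalize = FALSE)
}

#' @rdname mesh_primitives
#' @param z0,z1 cylinder cap positions (mm).
#' @param n number of angular segments.
#' @export
mesh_cylinder <- function(radius = 10, z0 = -10, z1 = 10,
                          center = c(0, 0), n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- center[1] + radius * cos(th)
  y <- center[2] + radius * sin(th)
  # vertices: bottom ring, top ring, bottom center, top center
  v <- rbind(cbind(x, y, z0), cbind(x, y, z1),
             c(center[1], center[2], z0), c(center[1], center[2], z1))
  ib <- seq_len(n); it <- n + ib
  nxt <- c(2:n, 1L)
  side <- rbind(cbind(ib, ib[nxt], it),
                cbind(ib[nxt], it[nxt], it))
  capb <- cbind(2L * n + 1L, ib[nxt], ib)           # bottom cap faces -z
  capt <- cbind(2L * n + 2L, it, it[nxt])           # top cap faces +z
  triangular_mesh(v, rbind(side, capb, capt), normalize = TRUE)
}

#' @rdname mesh_primitives
#' @param ring_radius distance from the torus axis (z) to the tube centre
#'   (mm).
#' @param tube_radius tube radius (mm).
#' @param nu,nv angular resolution around the axis and around the tube.
#' @export
mesh_torus <- function(ring_radius = 10, tube_radius = 3,
                       center = c(0, 0, 0), nu = 96, nv = 48) {
  u <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  w <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  g <- expand.grid(u = u, w = w)
  r <- ring_radius + tube_radius * cos(g$w)
  v <- cbind(center[1] + r * cos(g$u),
             center[2] + r * sin(g$u),
             center[3] + tube_radius * sin(g$w))
  idx <- function(i, j) (j - 1L) * nu + i         # i along u, j along w
  i <- rep(seq_len(nu), nv); j <- rep(seq_len(nv), each = nu)
  i2 <- ifelse(i == nu, 1L, i + 1L)
  j2 <- ifelse(j == nv, 1L, j + 1L)
  f <- rbind(cbind(idx(i, j), idx(i2, j), idx(i2, j2)),
             cbind(idx(i, j), idx(i2, j2), idx(i, j2)))
  triangular_mesh(v, f, normalize = TRUE)
}
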