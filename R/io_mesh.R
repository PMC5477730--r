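#' Read and write triangular meshes (STL, PLY)
#'
#' STL is read in both its ASCII and binary form (auto-detected); STL
#' stores a triangle soup, so identical vertices are merged on read before
#' the mesh is re-oriented. PLY support covers the common ASCII dialect
#' with `vertex` x/y/z properties and triangular `face` lists.
#'
#' @param path file path.
#' @param normalize passed to [triangular_mesh()]; re-orients faces after
#'   reading (exported meshes often have unreliable winding).
#' @return a [triangular_mesh()].
#' @export
read_stl <- function(path, normalize = TRUE) {
  bytes <- readBin(path, "raw", n = file.size(path))
  sniff <- function(n) {
    b <- bytes[seq_len(min(n, length(bytes)))]
    rawToChar(b[b > as.raw(0L) & b < as.raw(128L)])  # binary payload bytes
  }
  is_ascii <- grepl("^\\s*solid", sniff(200L), useBytes = TRUE) &&
    grepl("facet", sniff(1000L), useBytes = TRUE)
  if (is_ascii) {
    txt <- rawToChar(bytes)
    toks <- regmatches(txt, gregexpr("vertex\\s+\\S+\\s+\\S+\\s+\\S+", txt))[[1L]]
    xyz <- t(vapply(strsplit(toks, "\\s+"), function(w) as.numeric(w[2:4]),
                    numeric(3L)))
  } else {
    ntri <- readBin(bytes[81:84], "integer", n = 1L, size = 4L,
                    endian = "little")
    rec <- bytes[-(1:84)]
    if (length(rec) < ntri * 50L) stop("read_stl: truncated binary STL")
    # each 50-byte record: 12 floats (normal + 3 vertices) + 2 attribute bytes
    idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L + rep(1:48, ntri)
    fl <- readBin(rec[idx], "double", n = ntri * 12L, size = 4L,
                  endian = "little")
    m <- matrix(fl, ncol = 12L, byrow = TRUE)
    xyz <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                 m[, 10:12, drop = FALSE])
    # rows interleave triangle vertices 1,2,3; reorder to per-triangle
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    xyz <- xyz[ord, , drop = FALSE]
  }
  if (nrow(xyz) %% 3L != 0L) stop("read_stl: vertex count not divisible by 3")
  key <- paste(round(xyz[, 1L], 9L), round(xyz[, 2L], 9L), round(xyz[, 3L], 9L))
  ukey <- unique(key)
  vid <- match(key, ukey)
  verts <- xyz[match(ukey, key), , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  triangular_mesh(verts, faces, normalize = normalize)
}

#' @rdname read_stl
#' @param mesh a [triangular_mesh()].
#' @param binary write binary STL (default) or ASCII.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, binary = TRUE, name = "ctvdelta") {
  stopifnot(inherits(mesh, "triangular_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  nrm <- cbind(nx / nn, ny / nn, nz / nn)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("binary STL", name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- cbind(nrm, a, b, c_)
    for (i in seq_len(nrow(f))) {
      writeBin(as.double(block[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    tri_txt <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      nrm[, 1L], nrm[, 2L], nrm[, 3L],
      a[, 1L], a[, 2L], a[, 3L], b[, 1L], b[, 2L], b[, 3L],
      c_[, 1L], c_[, 2L], c_[, 3L])
    writeLines(tri_txt, con)
    writeLines(sprintf("endsolid %s", name), con)
  }
  invisible(path)
}

#' @rdname read_stl
#' @export
read_ply <- function(path, normalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1L] != "ply") stop("not a PLY file: ", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("read_ply: missing end_header")
  hdr <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", hdr))) {
    stop("read_ply: only ascii PLY is supported")
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(endh + 1L):length(lines)]
  vrows <- body[seq_len(nv)]
  verts <- t(vapply(strsplit(trimws(vrows), "\\s+"),
                    function(w) as.numeric(w[1:3]), numeric(3L)))
  frows <- body[nv + seq_len(nf)]
  faces <- t(vapply(strsplit(trimws(frows), "\\s+"), function(w) {
    k <- as.integer(w[1L])
    if (k != 3L) stop("read_ply: non-triangular face")
    as.integer(w[2:4]) + 1L
  }, integer(3L)))
  triangular_mesh(verts, faces, normalize = normalize)
}

#' @rdname read_stl
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangular_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment produced by ctvdelta",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                     mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
  invisible(path)
}
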