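#' Read and write NRRD volumes
#'
#' Minimal NRRD 4 reader/writer covering the dialect this package emits:
#' 3-dimensional volumes, little-endian `raw`, `ascii` or `gzip` encodings,
#' axis-aligned `space directions` and a `space origin`. Structure masks
#' are stored as `uint8` (0/1) and dose grids as `double` in Gy with the
#' prescription carried in a `ctvdelta:prescription` key.
#'
#' @param path file path.
#' @param as `"auto"` maps `uint8`/`uchar` volumes to a
#'   [structure_mask()] and floating-point volumes to a [dose_grid()];
#'   `"mask"`/`"dose"` force the interpretation.
#' @return a `structure_mask` or `dose_grid`.
#' @export
read_nrrd <- function(path, as = c("auto", "mask", "dose")) {
  as <- match.arg(as)
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  split_at <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p - prev <= 1L ||
        (p - prev == 2L && bytes[p - 1L] == as.raw(13L))) {
      split_at <- p
      break
    }
    prev <- p
  }
  if (is.na(split_at)) stop("read_nrrd: malformed header (no blank line)")
  hdr_lines <- strsplit(rawToChar(bytes[seq_len(split_at)]), "\r?\n")[[1L]]
  payload <- bytes[-seq_len(split_at)]
  if (!grepl("^NRRD000", hdr_lines[1L])) stop("not a NRRD file: ", path)
  fields <- list(); keys <- list()
  for (line in hdr_lines[-1L]) {
    if (line == "" || grepl("^#", line)) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1L]]
      keys[[trimws(kv[1L])]] <- trimws(kv[2L])
    } else {
      kv <- strsplit(line, ": ", fixed = TRUE)[[1L]]
      fields[[tolower(trimws(kv[1L]))]] <- trimws(paste(kv[-1L], collapse = ": "))
    }
  }
  type <- fields[["type"]]
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1L]])
  if (length(sizes) != 3L) stop("read_nrrd: only 3D volumes are supported")
  enc <- fields[["encoding"]]
  n <- prod(sizes)

  parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1L]])
  origin <- if (!is.null(fields[["space origin"]])) {
    parse_vec(fields[["space origin"]])
  } else c(0, 0, 0)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- strsplit(fields[["space directions"]], "\\)\\s*\\(")[[1L]]
    dm <- t(vapply(dirs, parse_vec, numeric(3L)))
    if (any(abs(dm[!diag(3) > 0]) > 1e-9)) {
      stop("read_nrrd: only axis-aligned space directions are supported")
    }
    spacing <- diag(dm)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
  }

  is_int <- type %in% c("uchar", "uint8", "uint8_t", "unsigned char")
  if (enc == "ascii" || enc == "text" || enc == "txt") {
    vals <- scan(text = rawToChar(payload), what = double(), n = n,
                 quiet = TRUE)
  } else {
    if (enc == "gzip" || enc == "gz") {
      payload <- memDecompress(payload, type = "gzip")
    } else if (enc != "raw") {
      stop("read_nrrd: unsupported encoding: ", enc)
    }
    vals <- if (is_int) {
      as.numeric(readBin(payload, "integer", n = n, size = 1L, signed = FALSE))
    } else if (type == "float") {
      readBin(payload, "double", n = n, size = 4L, endian = "little")
    } else if (type == "double") {
      readBin(payload, "double", n = n, size = 8L, endian = "little")
    } else {
      stop("read_nrrd: unsupported type: ", type)
    }
  }
  if (length(vals) < n) stop("read_nrrd: truncated data")
  arr <- array(vals[seq_len(n)], sizes)
  if (as == "mask" || (as == "auto" && is_int)) {
    structure_mask(origin, spacing, arr != 0)
  } else {
    rx <- if (!is.null(keys[["ctvdelta:prescription"]])) {
      as.numeric(keys[["ctvdelta:prescription"]])
    } else 70
    dose_grid(origin, spacing, arr, prescription = rx)
  }
}

#' @rdname read_nrrd
#' @param x a [structure_mask()] or [dose_grid()].
#' @param encoding one of `"raw"`, `"gzip"`, `"ascii"`.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "gzip", "ascii")) {
  encoding <- match.arg(encoding)
  is_mask <- inherits(x, "structure_mask")
  if (!is_mask && !inherits(x, "dose_grid")) {
    stop("write_nrrd: x must be a structure_mask or dose_grid")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# produced by ctvdelta",
    sprintf("type: %s", if (is_mask) "uint8" else "double"),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", x$shape[1], x$shape[2], x$shape[3]),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            x$spacing[1], x$spacing[2], x$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    sprintf("encoding: %s", encoding),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            x$origin[1], x$origin[2], x$origin[3]))
  if (!is_mask) {
    hdr <- c(hdr, sprintf("ctvdelta:prescription:=%.9g", x$prescription))
  }
  writeLines(c(hdr, ""), con)
  vals <- if (is_mask) as.integer(x$occupancy) else as.double(x$dose)
  if (encoding == "ascii") {
    writeLines(paste(vals, collapse = " "), con)
  } else {
    payload <- if (is_mask) {
      as.raw(vals)
    } else {
      writeBin(vals, raw(), size = 8L, endian = "little")
    }
    if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
  }
  invisible(path)
}
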