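#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL. Duplicate vertices are merged exactly (by
#' coordinate triple) so downstream topology checks work; triangle order and
#' coordinates are preserved to float precision (binary STL stores 32-bit
#' floats).
#'
#' @param path path to an `.stl` file.
#' @return a [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = min(84, sz))
  if (length(header) < 15)
    stop(sprintf("STL parse error at byte 0: file too short (%d bytes)", sz))
  is_binary <- FALSE
  if (length(header) == 84) {
    ntri <- readBin(header[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    tri <- matrix(NA_real_, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      if (length(rec) < 12)
        stop(sprintf("STL parse error at byte %d: truncated facet %d",
                     84 + 50 * (i - 1), i))
      readBin(con, "raw", n = 2)  # attribute byte count
      tri[3 * i - 2, ] <- rec[4:6]
      tri[3 * i - 1, ] <- rec[7:9]
      tri[3 * i, ]     <- rec[10:12]
    }
  } else {
    bytes <- c(header, readBin(con, "raw", n = sz))
    if (any(bytes == as.raw(0)))
      stop(sprintf("STL parse error at byte %d: binary data in non-binary file",
                   which(bytes == as.raw(0))[1] - 1))
    txt <- rawToChar(bytes)
    if (!grepl("^\\s*solid", txt))
      stop("STL parse error at byte 0: neither a valid binary header nor 'solid'")
    m <- gregexpr("vertex\\s+([-+0-9.eE]+)\\s+([-+0-9.eE]+)\\s+([-+0-9.eE]+)", txt)
    toks <- regmatches(txt, m)[[1]]
    if (!length(toks)) stop("STL parse error: ASCII file contains no vertices")
    vals <- lapply(strsplit(toks, "\\s+"), function(x) as.numeric(x[2:4]))
    tri <- do.call(rbind, vals)
    if (nrow(tri) %% 3 != 0)
      stop(sprintf("STL parse error: vertex count %d not a multiple of 3", nrow(tri)))
    nfac <- length(gregexpr("facet normal", txt)[[1]])
    if (nfac != nrow(tri) / 3)
      stop(sprintf("STL parse error: %d facets declared but %d vertex triples found",
                   nfac, nrow(tri) / 3))
  }
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Write an STL surface mesh
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param binary write binary (default) or ASCII STL.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  nrm <- cbind(nx / len, ny / len, nz / len)
  n <- nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("scaffem binary STL", width = -80)), con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    rec <- matrix(0, 12, n)
    rec[1:3, ] <- t(nrm)
    rec[4:6, ] <- t(a)
    rec[7:9, ] <- t(b)
    rec[10:12, ] <- t(c3)
    for (i in seq_len(n)) {
      writeBin(rec[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    lines <- character(7 * n + 2)
    lines[1] <- "solid scaffem"
    idx <- 2L
    for (i in seq_len(n)) {
      lines[idx:(idx + 6)] <- c(
        sprintf("  facet normal %s %s %s", fmt(nrm[i, 1]), fmt(nrm[i, 2]), fmt(nrm[i, 3])),
        "    outer loop",
        sprintf("      vertex %s %s %s", fmt(a[i, 1]), fmt(a[i, 2]), fmt(a[i, 3])),
        sprintf("      vertex %s %s %s", fmt(b[i, 1]), fmt(b[i, 2]), fmt(b[i, 3])),
        sprintf("      vertex %s %s %s", fmt(c3[i, 1]), fmt(c3[i, 2]), fmt(c3[i, 3])),
        "    endfacet" , "")
      lines[idx + 5] <- "    endloop"
      lines[idx + 6] <- "  endfacet"
      idx <- idx + 7L
    }
    lines[length(lines)] <- "endsolid scaffem"
    writeLines(lines, path)
  }
  invisible(path)
}
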