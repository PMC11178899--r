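# STL and PLY input/output.
#
# STL stores a triangle soup (three explicit vertices per facet); reading
# welds duplicated vertices back into an indexed mesh. Binary layout:
# 80-byte header, uint32 facet count, then 50 bytes per facet
# (normal 3 x float32, vertices 9 x float32, uint16 attribute).

weld_vertices <- function(soup, faces, tolerance = 0) {
  if (tolerance > 0) {
    key_mat <- round(soup / tolerance) * tolerance
  } else {
    key_mat <- soup
  }
  # %a keys give exact bitwise identity for tolerance = 0
  key <- paste(sprintf("%a", key_mat[, 1]),
               sprintf("%a", key_mat[, 2]),
               sprintf("%a", key_mat[, 3]))
  first <- !duplicated(key)
  map <- match(key, key[first])
  faces_new <- matrix(map[faces], ncol = 3)
  list(positions = soup[first, , drop = FALSE], faces = faces_new)
}

stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 80)
  n <- readBin(con, "integer", 1, size = 4)
  # a well-formed binary file has exactly 84 + 50 n bytes; ASCII almost never
  !is.na(n) && n >= 0 && size == 84 + 50 * n
}

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (the dialect is auto-detected from the byte
#' layout) and welds duplicated facet vertices into an indexed [trimesh].
#' Face winding is preserved as stored; normals embedded in the file are
#' ignored and should be recomputed with [vertex_normals()].
#'
#' @param path path to an STL file.
#' @param tolerance welding tolerance in mm. The default `0` welds only
#'   bitwise-identical coordinates, which is what STL exporters produce and
#'   avoids collapsing genuinely close anatomy; a positive value snaps
#'   coordinates to a grid of that pitch before welding.
#' @return a [trimesh] with `provenance` recording path and dialect.
#' @export
starts_with_solid <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  identical(readBin(con, "raw", 5), charToRaw("solid"))
}

read_stl <- function(path, tolerance = 0) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (stl_is_binary(path) || !starts_with_solid(path)) {
    out <- read_stl_binary(path)
    dialect <- "binary"
  } else {
    out <- read_stl_ascii(path)
    dialect <- "ascii"
  }
  if (nrow(out$faces) == 0L) stopf("empty STL mesh: %s", path)
  w <- weld_vertices(out$soup, out$faces, tolerance)
  trimesh(w$positions, w$faces,
          provenance = list(path = path, format = "stl", dialect = dialect))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", 50 * n)
  if (length(raw) < 50 * n)
    stopf("truncated binary STL: expected %d bytes from offset 84, got %d",
          50 * n, length(raw))
  dim(raw) <- c(50L, n)
  floats <- readBin(as.vector(raw[1:48, , drop = FALSE]), "double",
                    n = 12L * n, size = 4L, endian = "little")
  per_facet <- matrix(floats, nrow = 12L)  # rows 1:3 normal, 4:12 vertices
  soup <- matrix(as.vector(per_facet[4:12, , drop = FALSE]),
                 ncol = 3, byrow = TRUE)
  if (!all(is.finite(soup))) stopf("non-finite coordinate in %s", path)
  faces <- matrix(seq_len(3L * n), ncol = 3, byrow = TRUE)
  list(soup = soup, faces = faces)
}

read_stl_ascii <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE)
  vi <- which(tokens == "vertex")
  if (length(vi) == 0L || length(vi) %% 3L != 0L)
    stopf("malformed ASCII STL (%d 'vertex' tokens, need a multiple of 3): %s",
          length(vi), path)
  coords <- suppressWarnings(
    as.numeric(tokens[rep(vi, each = 3) + rep(1:3, length(vi))]))
  if (anyNA(coords)) stopf("non-numeric vertex coordinate in %s", path)
  soup <- matrix(coords, ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(nrow(soup)), ncol = 3, byrow = TRUE)
  list(soup = soup, faces = faces)
}

#' Write an STL surface mesh
#'
#' Binary STL stores coordinates as 32-bit floats, so
#' `read_stl(write_stl(m))` reproduces positions to float32 precision and
#' the same face multiset. Facet normals are recomputed from winding.
#'
#' @param mesh a [trimesh]; must have at least one face.
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (n_faces(mesh) == 0L) stopf("refusing to write an empty mesh")
  p <- mesh$positions
  f <- mesh$faces
  a <- p[f[, 1], , drop = FALSE]
  b <- p[f[, 2], , drop = FALSE]
  c3 <- p[f[, 3], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- normalize_rows(nrm)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    rec <- cbind(nrm, a, b, c3)            # m x 12, facet record order
    fraw <- writeBin(as.vector(t(rec)), raw(), size = 4, endian = "little")
    dim(fraw) <- c(48L, nrow(f))
    out <- rbind(fraw, matrix(as.raw(0), 2L, nrow(f)))
    writeBin(as.vector(out), con)
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c("solid mesh",
               as.vector(rbind(paste("facet normal", fmt(nrm)),
                               "outer loop",
                               paste("vertex", fmt(a)),
                               paste("vertex", fmt(b)),
                               paste("vertex", fmt(c3)),
                               "endloop",
                               "endfacet")),
               "endsolid mesh")
    writeLines(lines, path)
  }
  invisible(path)
}

# diverging colormap centered at 0: blue -> light gray -> red; the red
# channel is strictly increasing in the scalar so sign ordering survives
# 8-bit quantization
gradient_colors <- function(values) {
  m <- max(abs(values))
  t <- if (m > 0) values / m else rep(0, length(values))
  ramp <- grDevices::colorRamp(c("#0000FF", "#F0F0F0", "#FF0000"),
                               space = "rgb")
  col <- ramp((t + 1) / 2)
  storage.mode(col) <- "integer"
  col
}

#' Write a mesh with a per-vertex scalar field as colored PLY
#'
#' Exports binary little-endian PLY with per-vertex RGB from a diverging
#' colormap centered at 0 (positive values red, negative blue — red marks
#' regions where pushing the surface outward raises the score) and the raw
#' scalar stored as a float vertex property `gradient`, so exact values
#' survive a round-trip through [read_ply()].
#'
#' @param mesh a [trimesh].
#' @param vertex_scalars numeric vector, one value per vertex.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colored_surface <- function(mesh, vertex_scalars, path) {
  nv <- n_vertices(mesh)
  if (length(vertex_scalars) != nv)
    stopf("need %d vertex scalars, got %d", nv, length(vertex_scalars))
  if (!all(is.finite(vertex_scalars))) stopf("non-finite vertex scalar")
  col <- gradient_colors(vertex_scalars)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("ply",
              "format binary_little_endian 1.0",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green",
              "property uchar blue",
              "property float gradient",
              sprintf("element face %d", n_faces(mesh)),
              "property list uchar int vertex_indices",
              "end_header")
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  pos_raw <- writeBin(as.vector(t(mesh$positions)), raw(), size = 4,
                      endian = "little")
  dim(pos_raw) <- c(12L, nv)
  grad_raw <- writeBin(as.numeric(vertex_scalars), raw(), size = 4,
                       endian = "little")
  dim(grad_raw) <- c(4L, nv)
  vrec <- rbind(pos_raw, matrix(as.raw(t(col)), 3L, nv), grad_raw)
  writeBin(as.vector(vrec), con)
  if (n_faces(mesh) > 0L) {
    fidx <- writeBin(as.integer(t(mesh$faces) - 1L), raw(), size = 4,
                     endian = "little")
    dim(fidx) <- c(12L, n_faces(mesh))
    frec <- rbind(matrix(as.raw(3L), 1L, n_faces(mesh)), fidx)
    writeBin(as.vector(frec), con)
  }
  invisible(path)
}

#' Read a colored PLY surface written by [write_colored_surface()]
#'
#' Minimal reader for the binary little-endian layout this package writes
#' (xyz float32, RGB uchar, float32 `gradient`, uchar-int face lists).
#'
#' @param path a PLY file.
#' @return list with `mesh` (a [trimesh]), `gradient` (numeric per vertex)
#'   and `rgb` (integer n x 3 matrix).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ch <- character()
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0L) stopf("unterminated PLY header: %s", path)
      if (b == as.raw(10L)) break
      ch <- c(ch, rawToChar(b))
    }
    line <- paste(ch, collapse = "")
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (!any(grepl("^format binary_little_endian", header)))
    stopf("unsupported PLY format in %s", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  vraw <- readBin(con, "raw", 19L * nv)
  dim(vraw) <- c(19L, nv)
  pos <- matrix(readBin(as.vector(vraw[1:12, , drop = FALSE]), "double",
                        n = 3L * nv, size = 4, endian = "little"),
                ncol = 3, byrow = TRUE)
  rgb <- matrix(as.integer(vraw[13:15, , drop = FALSE]), ncol = 3,
                byrow = TRUE)
  grad <- readBin(as.vector(vraw[16:19, , drop = FALSE]), "double",
                  n = nv, size = 4, endian = "little")
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    fraw <- readBin(con, "raw", 13L * nf)
    dim(fraw) <- c(13L, nf)
    faces <- matrix(readBin(as.vector(fraw[2:13, , drop = FALSE]), "integer",
                            n = 3L * nf, size = 4, endian = "little"),
                    ncol = 3, byrow = TRUE) + 1L
  }
  list(mesh = trimesh(pos, faces,
                      provenance = list(path = path, format = "ply")),
       gradient = grad, rgb = rgb)
}

#' Write a gradient field as a plain-text two-column dump
#'
#' @param values numeric per-vertex values.
#' @param path output path.
#' @return `path`, invisibly. Columns: 1-based vertex index, value.
#' @export
write_gradient_txt <- function(values, path) {
  write.table(data.frame(vertex = seq_along(values), value = values),
              path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
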