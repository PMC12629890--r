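#' Read a triangle mesh from file
#'
#' Supported formats: STL (ASCII or binary, auto-detected), PLY (ASCII) and
#' legacy VTK polydata (ASCII).  STL stores one vertex triple per facet
#' corner, so identical corners are merged back into a shared-vertex mesh on
#' read.  Coordinates are taken as native-space millimetres, RAS axis order.
#'
#' @param path file path; format is inferred from the extension
#'   (`.stl`, `.ply`, `.vtk`) unless `format` is given.
#' @param format optional explicit format, one of `"stl"`, `"ply"`, `"vtk"`.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- tolower(format %||% file_ext(path))
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk(path),
         stop("unsupported mesh format: ", format))
}

#' Write a triangle mesh to file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format inferred from extension unless given.
#' @param format `"stl"`, `"ply"` or `"vtk"`.
#' @param binary for STL only: write the 50-byte-per-facet binary layout
#'   instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(is_triangle_mesh(mesh))
  format <- tolower(format %||% file_ext(path))
  switch(format,
         stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         vtk = write_vtk(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || identical(a, "")) b else a

# ---- STL ------------------------------------------------------------------

facet_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  idx <- as.vector(t(f))             # corner order a1 b1 c1 a2 b2 c2 ...
  v[idx, , drop = FALSE]
}

# rebuild a shared-vertex mesh from a (3m x 3) corner soup by exact
# coordinate match (round-trip safe: shared corners are written identically)
mesh_from_corners <- function(corners) {
  key <- paste(corners[, 1], corners[, 2], corners[, 3], sep = "_")
  uk <- !duplicated(key)
  verts <- corners[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

write_stl_ascii <- function(mesh, path) {
  n <- face_normals(mesh)
  co <- facet_corners(mesh)
  m <- nrow(mesh$faces)
  fmt <- function(x) sprintf("%.10g", x)
  lines <- character(7 * m + 2)
  lines[1] <- "solid stncoalign"
  base <- 1
  for (i in seq_len(m)) {
    j <- 3 * (i - 1)
    lines[base + 7 * (i - 1) + 1:7] <- c(
      paste("facet normal", fmt(n[i, 1]), fmt(n[i, 2]), fmt(n[i, 3])),
      "  outer loop",
      paste("    vertex", fmt(co[j + 1, 1]), fmt(co[j + 1, 2]), fmt(co[j + 1, 3])),
      paste("    vertex", fmt(co[j + 2, 1]), fmt(co[j + 2, 2]), fmt(co[j + 2, 3])),
      paste("    vertex", fmt(co[j + 3, 1]), fmt(co[j + 3, 2]), fmt(co[j + 3, 3])),
      "  endloop",
      "endfacet")
  }
  lines[length(lines)] <- "endsolid stncoalign"
  writeLines(lines, path)
}

write_stl_binary <- function(mesh, path) {
  n <- face_normals(mesh)
  co <- facet_corners(mesh)
  m <- nrow(mesh$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("stncoalign binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  for (i in seq_len(m)) {
    j <- 3 * (i - 1)
    rec <- c(n[i, ], t(co[j + 1:3, , drop = FALSE]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  # ASCII files start with "solid" and will not match the size formula
  if (identical(expected, as.numeric(sz))) return(TRUE)
  !grepl("^\\s*solid", rawToChar(head[head != as.raw(0)]))
}

read_stl <- function(path) {
  if (is_binary_stl(path)) return(read_stl_binary(path))
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  }
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  mesh_from_corners(nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  m <- readBin(con, "integer", 1, size = 4, endian = "little")
  recs <- matrix(NA_real_, 3 * m, 3)
  for (i in seq_len(m)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    recs[3 * (i - 1) + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  mesh_from_corners(recs)
}

# ---- PLY (ASCII) ----------------------------------------------------------

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              "comment stncoalign mesh",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  body_v <- sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3])
  body_f <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, body_v, body_f), path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("^format ascii", lines))) stop("only ASCII PLY is supported")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY: no end_header")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vlines <- lines[endh + seq_len(nv)]
  flines <- lines[endh + nv + seq_len(nf)]
  v <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  f <- t(vapply(strsplit(trimws(flines), "\\s+"), function(x) {
    if (as.integer(x[1]) != 3L) stop("only triangle faces are supported")
    as.integer(x[2:4])
  }, integer(3)))
  triangle_mesh(v, f + 1L)
}

# ---- legacy VTK polydata (ASCII) ------------------------------------------

write_vtk <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c("# vtk DataFile Version 3.0",
             "stncoalign mesh", "ASCII", "DATASET POLYDATA",
             sprintf("POINTS %d double", nrow(v)),
             sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
             sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1])) stop("not a legacy VTK file: ", path)
  if (!any(toupper(trimws(lines)) == "ASCII")) stop("only ASCII VTK is supported")
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("malformed VTK: no POINTS block")
  nv <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1]][2])
  # POINTS values may wrap lines arbitrarily: collect tokens until 3*nv read
  toks <- character()
  i <- ip + 1
  while (length(toks) < 3 * nv) {
    toks <- c(toks, strsplit(trimws(lines[i]), "\\s+")[[1]])
    i <- i + 1
  }
  v <- matrix(as.numeric(toks[1:(3 * nv)]), ncol = 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS", lines)[1]
  if (is.na(ipoly)) stop("malformed VTK: no POLYGONS block")
  nf <- as.integer(strsplit(trimws(lines[ipoly]), "\\s+")[[1]][2])
  toks <- character()
  i <- ipoly + 1
  while (length(toks) < 4 * nf) {
    toks <- c(toks, strsplit(trimws(lines[i]), "\\s+")[[1]])
    i <- i + 1
  }
  cells <- matrix(as.integer(toks[1:(4 * nf)]), ncol = 4, byrow = TRUE)
  if (any(cells[, 1] != 3L)) stop("only triangle faces are supported")
  triangle_mesh(v, cells[, 2:4] + 1L)
}
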