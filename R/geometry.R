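#' Triangle mesh in native-space millimetres
#'
#' Light container for a closed triangulated surface such as the STN mesh
#' segmented from preoperative imaging.  Vertices are stored as an n x 3
#' numeric matrix (mm, RAS axis order assumed for file I/O) and faces as an
#' m x 3 integer matrix of 1-based vertex indices.  All inclusion and
#' distance queries in this package require the mesh to be watertight and
#' consistently oriented; use [validate_mesh()] to check.
#'
#' @param vertices numeric matrix (n x 3), vertex coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices per triangle.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' cube <- unit_cube_mesh()
#' validate_mesh(cube)$watertight
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Validate a triangle mesh
#'
#' Checks the structural invariants required before inclusion or distance
#' queries: valid face indices, three distinct vertices per face, minimum
#' size, closedness (every undirected edge shared by exactly two faces) and
#' consistent orientation (every directed edge used exactly once).
#'
#' @param mesh a [triangle_mesh()].
#' @return A list with logical flags `watertight`, `oriented`,
#'   `indices_valid`, `faces_distinct`, `size_ok`, counts `n_vertices` /
#'   `n_faces`, an overall flag `ok`, and a character vector `problems`
#'   naming each violated invariant (empty when the mesh is clean).
#' @export
validate_mesh <- function(mesh) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  nf <- nrow(f)
  problems <- character()

  indices_valid <- nf == 0L || (all(f >= 1L) && all(f <= nv) && !anyNA(f))
  if (!indices_valid) problems <- c(problems, "face indices out of range")

  faces_distinct <- indices_valid &&
    all(f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3])
  if (!faces_distinct) problems <- c(problems, "degenerate face (repeated vertex)")

  size_ok <- nv >= 4L && nf >= 4L
  if (!size_ok) problems <- c(problems, "fewer than 4 vertices or 4 faces")

  watertight <- FALSE
  oriented <- FALSE
  if (indices_valid && faces_distinct && nf > 0L) {
    # directed edges as scalar keys i * (nv+1) + j
    from <- c(f[, 1], f[, 2], f[, 3])
    to <- c(f[, 2], f[, 3], f[, 1])
    key_dir <- as.numeric(from) * (nv + 1) + as.numeric(to)
    key_und <- pmin(from, to) * (nv + 1) + as.numeric(pmax(from, to))
    oriented <- !any(duplicated(key_dir))
    tab <- table(key_und)
    watertight <- all(tab == 2L) && oriented
    if (!watertight) problems <- c(problems, "mesh not watertight (open or non-manifold edges)")
    if (!oriented) problems <- c(problems, "inconsistent face orientation")
  } else {
    problems <- c(problems, "mesh not watertight (open or non-manifold edges)")
  }

  list(watertight = watertight, oriented = oriented,
       indices_valid = indices_valid, faces_distinct = faces_distinct,
       size_ok = size_ok, n_vertices = nv, n_faces = nf,
       ok = indices_valid && faces_distinct && size_ok && watertight,
       problems = problems)
}

assert_valid_mesh <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (!rep$ok) {
    stop("invalid mesh: ", paste(rep$problems, collapse = "; "), call. = FALSE)
  }
  invisible(rep)
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume: sum of signed tetrahedra spanned by the origin
#' and each face.  Positive for outward-oriented meshes.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return Enclosed volume in mm^3 (signed; take `abs()` if orientation is
#'   unknown).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6
}

#' Volume centroid of the solid enclosed by a mesh
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return 3-vector, centroid of the enclosed solid in mm.
#' @export
mesh_centroid <- function(mesh) {
  assert_valid_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(det) / 6
  if (abs(vol) < 1e-12) stop("degenerate mesh: enclosed volume is zero")
  # centroid of tetra (0, a, b, c) is (a+b+c)/4, weighted by signed volume
  num <- colSums((a + b + c_) / 4 * (det / 6))
  as.numeric(num / vol)
}

#' Isotropically scale a mesh about a centre
#'
#' Maps every vertex v to `center + alpha * (v - center)`; face topology is
#' unchanged.  This is the "scaled mesh alpha*M" used by the co-alignment
#' cost: the imaging STN grown or shrunk about its own centroid to absorb
#' the disparity between the MRI hypointensity and the electrophysiological
#' STN.
#'
#' @param mesh a [triangle_mesh()].
#' @param alpha positive scalar scale factor.
#' @param center 3-vector fixed point (default: volume centroid of `mesh`).
#' @return The scaled [triangle_mesh()].
#' @export
scale_mesh <- function(mesh, alpha, center = mesh_centroid(mesh)) {
  stopifnot(is_triangle_mesh(mesh))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a positive finite scalar")
  }
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  v <- sweep(sweep(mesh$vertices, 2, center, "-") * alpha, 2, center, "+")
  triangle_mesh(v, mesh$faces)
}

#' Point-in-mesh inclusion test
#'
#' Ray-crossing-parity test against a watertight mesh.  Points within
#' `tol` (default 1e-9 mm) of the surface count as inside; the choice is
#' cost-neutral for the co-alignment objective (the distance term vanishes
#' on the surface) but must be deterministic.
#'
#' @param points 3-vector or n x 3 matrix of query points (mm).
#' @param mesh a watertight [triangle_mesh()].
#' @param tol boundary tolerance in mm.
#' @return Logical vector, one entry per query point.
#' @export
point_in_mesh <- function(points, mesh, tol = 1e-9) {
  q <- mesh_query(points, mesh, tol = tol, inside = TRUE, dist = FALSE)
  q$inside
}

#' Unsigned distance from points to a mesh surface
#'
#' Minimum Euclidean distance from each query point to any triangle of the
#' surface (0 for points on the surface; positive both inside and outside).
#'
#' @inheritParams point_in_mesh
#' @return Numeric vector of distances in mm.
#' @export
distance_to_surface <- function(points, mesh) {
  q <- mesh_query(points, mesh, tol = 0, inside = FALSE, dist = TRUE)
  q$dist
}

# Shared entry to the compiled kernel: validates the mesh once and shapes
# the point input.  `inside = TRUE` requires watertightness; distance-only
# queries merely need a non-empty face list.
mesh_query <- function(points, mesh, tol = 1e-9, inside = TRUE, dist = TRUE) {
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0L) stop("empty mesh")
  if (inside) assert_valid_mesh(mesh)
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a single point must have length 3")
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have 3 columns")
  .mesh_query_cpp(points, mesh$vertices, mesh$faces, tol, inside, dist)
}

#' Axis-aligned unit cube mesh
#'
#' Convenience fixture: closed unit cube (8 vertices, 12 triangles) centred
#' at `center` with edge length `edge`, outward-oriented.
#'
#' @param center 3-vector cube centre (mm).
#' @param edge edge length (mm).
#' @return A watertight [triangle_mesh()].
#' @export
unit_cube_mesh <- function(center = c(0, 0, 0), edge = 1) {
  h <- edge / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, as.numeric(center), "+")
  # 12 outward-oriented triangles over the expand.grid vertex order
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  triangle_mesh(v, f)
}
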