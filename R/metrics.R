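#' Straight-line trajectory
#'
#' A trajectory is the infinite line through `anchor` with unit `direction`
#' plus the depth interval actually traversed, measured in mm along the
#' direction from the anchor.
#'
#' @param anchor 3-vector point on the line (mm).
#' @param direction 3-vector; normalised internally.
#' @param depth_span length-2 numeric, min/max depth along the direction.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(anchor, direction, depth_span) {
  anchor <- as.numeric(anchor)
  direction <- as.numeric(direction)
  stopifnot(length(anchor) == 3L, length(direction) == 3L,
            length(depth_span) == 2L)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must be non-zero")
  if (abs(nrm - 1) > 1e-12) direction <- direction / nrm
  depth_span <- sort(as.numeric(depth_span))
  if (depth_span[2] - depth_span[1] <= 0) stop("degenerate depth span")
  structure(list(anchor = anchor, direction = direction,
                 depth_span = depth_span),
            class = "trajectory")
}

#' Fraction of STN-labelled sites inside a mesh
#'
#' Among sites carrying an STN label (`label == 1`), the fraction whose
#' position lies inside the mesh — the agreement statistic reported before
#' and after co-alignment.
#'
#' @param sites a [recording_sites()] table.
#' @param mesh a watertight [triangle_mesh()].
#' @return Fraction in `[0, 1]`.
#' @export
fraction_inside <- function(sites, mesh) {
  sites <- recording_sites(sites)
  stn <- sites[sites$label == 1L, , drop = FALSE]
  if (nrow(stn) == 0L) stop("no STN-labelled sites")
  mean(point_in_mesh(site_positions(stn), mesh))
}

#' Total-least-squares line fit
#'
#' Fits the line through the centroid along the first principal axis of a
#' point cloud (orthogonal-distance regression, the standard fit for
#' electrode artefact points picked from intraoperative CT).  The direction
#' is oriented from the first toward the last point so depth increases with
#' acquisition order.
#'
#' @param points n x 3 matrix (n >= 2) of points (mm).
#' @return A [trajectory()] whose depth span covers the projections of the
#'   input points; residual RMS distance is attached as attribute
#'   `"residual_rms"`.
#' @export
fit_trajectory_line <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 2L) stop("need at least 2 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr, "-")
  if (max(abs(X)) < 1e-12) stop("all points coincide; line undefined")
  sv <- svd(X)
  dir <- sv$v[, 1]
  if (sum(dir * (points[nrow(points), ] - points[1, ])) < 0) dir <- -dir
  t <- as.numeric(X %*% dir)
  resid <- X - outer(t, dir)
  span <- range(t)
  if (diff(span) < 1e-12) span <- span + c(-0.5, 0.5)  # coincident projections
  tr <- trajectory(ctr, dir, span)
  attr(tr, "residual_rms") <- sqrt(mean(rowSums(resid^2)))
  tr
}

#' Mean perpendicular distance between two trajectories
#'
#' Samples `traj_a` along its depth span at `pitch` (default 0.5 mm, the
#' recording pitch) and averages the perpendicular point-to-line distance
#' to the infinite line of `traj_b`.  Distances along the depth direction
#' are excluded by construction — intraoperative imaging does not reliably
#' show the electrode tip, so only lateral discrepancy is meaningful.
#'
#' @param traj_a,traj_b [trajectory()] objects; their depth spans must
#'   overlap once `traj_a`'s endpoints are projected onto `traj_b`.
#' @param pitch sampling pitch along `traj_a` in mm.
#' @return Mean perpendicular distance in mm.
#' @export
lateral_distance <- function(traj_a, traj_b, pitch = 0.5) {
  stopifnot(inherits(traj_a, "trajectory"), inherits(traj_b, "trajectory"))
  t_a <- seq(traj_a$depth_span[1], traj_a$depth_span[2], by = pitch)
  pts <- sweep(outer(t_a, traj_a$direction), 2, traj_a$anchor, "+")
  # overlap check: projections of the sampled span onto traj_b's axis
  proj <- as.numeric(sweep(pts, 2, traj_b$anchor, "-") %*% traj_b$direction)
  if (max(proj) < traj_b$depth_span[1] || min(proj) > traj_b$depth_span[2]) {
    stop("trajectory depth spans do not overlap")
  }
  d <- sweep(pts, 2, traj_b$anchor, "-")
  along <- d %*% traj_b$direction
  perp <- d - outer(as.numeric(along), traj_b$direction)
  mean(sqrt(rowSums(perp^2)))
}

#' Dice overlap of two binary volumes
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (Dice 1), an empty versus non-empty mask scores 0.
#'
#' @param mask_a,mask_b logical/0-1 arrays with identical dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask dimensions differ")
  }
  a <- as.logical(mask_a)
  b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Voxelise a mesh on a regular grid
#'
#' Marks every voxel whose centre lies inside the mesh.  Needed to compare
#' meshes by Dice overlap; the result is resolution-dependent, so the grid
#' is recorded with the volume.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param voxel_size isotropic voxel edge in mm (default 0.2).
#' @param bounds optional 2 x 3 matrix (min row, max row) of the grid
#'   extent; defaults to the mesh bounding box padded by one voxel.  Pass a
#'   common `bounds` when two volumes will be compared.
#' @return Logical 3-D array with attributes `origin` (centre of the first
#'   voxel), `voxel_size` and `bounds`.
#' @export
voxelize_mesh <- function(mesh, voxel_size = 0.2, bounds = NULL) {
  assert_valid_mesh(mesh)
  if (!is.numeric(voxel_size) || voxel_size <= 0) stop("voxel_size must be positive")
  if (is.null(bounds)) {
    bb <- apply(mesh$vertices, 2, range)
    bounds <- rbind(bb[1, ] - voxel_size, bb[2, ] + voxel_size)
  }
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2L, ncol(bounds) == 3L)
  axes <- lapply(1:3, function(i) {
    seq(bounds[1, i] + voxel_size / 2, bounds[2, i], by = voxel_size)
  })
  dims <- vapply(axes, length, integer(1))
  if (any(dims == 0L)) {
    vol <- array(FALSE, dim = pmax(dims, 1L))
  } else {
    centres <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
    inside <- point_in_mesh(centres, mesh)
    vol <- array(inside, dim = dims)
  }
  attr(vol, "origin") <- vapply(axes, function(a) if (length(a)) a[1] else NA_real_,
                                numeric(1))
  attr(vol, "voxel_size") <- voxel_size
  attr(vol, "bounds") <- bounds
  vol
}

#' Dice overlap between two meshes via voxelisation
#'
#' Voxelises both meshes on one shared grid covering their joint bounding
#' box and returns the Dice coefficient, with the grid resolution attached
#' (Dice between surfaces is only defined relative to a discretisation).
#'
#' @param mesh_a,mesh_b watertight [triangle_mesh()] objects.
#' @param voxel_size isotropic grid resolution in mm (default 0.2).
#' @return Dice value with attribute `"voxel_size"`.
#' @export
mesh_dice <- function(mesh_a, mesh_b, voxel_size = 0.2) {
  bb <- rbind(pmin(apply(mesh_a$vertices, 2, min), apply(mesh_b$vertices, 2, min)) - voxel_size,
              pmax(apply(mesh_a$vertices, 2, max), apply(mesh_b$vertices, 2, max)) + voxel_size)
  va <- voxelize_mesh(mesh_a, voxel_size, bb)
  vb <- voxelize_mesh(mesh_b, voxel_size, bb)
  out <- dice_coefficient(va, vb)
  attr(out, "voxel_size") <- voxel_size
  out
}
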