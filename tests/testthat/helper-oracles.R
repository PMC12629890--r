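# Independent R oracles used to cross-check the compiled geometry kernels.
# These deliberately use different formulations than the C++ code:
# inclusion via the generalised winding number (solid angles) instead of
# ray parity, and point-triangle distance via barycentric projection plus
# explicit edge-segment distances instead of the region-walk algorithm.

# generalised winding number (van Oosterom & Strackee solid angle per face);
# |sum| > 2*pi => inside for a watertight surface
oracle_inside <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  A <- sweep(v[f[, 1], , drop = FALSE], 2, p)
  B <- sweep(v[f[, 2], , drop = FALSE], 2, p)
  C <- sweep(v[f[, 3], , drop = FALSE], 2, p)
  la <- sqrt(rowSums(A^2)); lb <- sqrt(rowSums(B^2)); lc <- sqrt(rowSums(C^2))
  det <- A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
         A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
         A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])
  denom <- la * lb * lc + rowSums(A * B) * lc + rowSums(B * C) * la +
           rowSums(C * A) * lb
  omega <- 2 * atan2(det, denom)
  abs(sum(omega)) > 2 * pi
}

# ray-crossing parity with a caller-chosen ray direction (second independent
# route; used with directions different from the kernel's built-in set)
oracle_inside_parity <- function(p, mesh, dir = c(0.123, 0.456, 0.789)) {
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices
  f <- mesh$faces
  crossings <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    e1 <- b - a; e2 <- c - a
    pv <- c(dir[2] * e2[3] - dir[3] * e2[2],
            dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- p - a
    u <- sum(tv * pv) / det
    if (u < 0 || u > 1) next
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
            tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    w <- sum(dir * qv) / det
    if (w < 0 || u + w > 1) next
    t <- sum(e2 * qv) / det
    if (t > 0) crossings <- crossings + 1
  }
  crossings %% 2 == 1
}

# distance from p to segment [a, b]
seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# exhaustive point-to-surface distance: per triangle, orthogonal projection
# if its barycentric coordinates are non-negative, else the minimum of the
# three edge-segment distances
oracle_distance <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- Inf
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    e1 <- b - a; e2 <- c - a
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sum(n^2)
    d <- Inf
    if (nn > 1e-24) {
      w <- p - a
      # barycentric coordinates of the in-plane projection
      d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
      w1 <- sum(w * e1); w2 <- sum(w * e2)
      den <- d11 * d22 - d12^2
      u <- (d22 * w1 - d12 * w2) / den
      vv <- (d11 * w2 - d12 * w1) / den
      if (u >= 0 && vv >= 0 && u + vv <= 1) {
        d <- abs(sum(w * n)) / sqrt(nn)
      }
    }
    if (!is.finite(d)) {
      d <- min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
    }
    best <- min(best, d)
  }
  best
}

# mesh volume by an independent route: Monte-Carlo not needed; use the
# closed-form divergence sum but over a translated copy (robustness check
# left to the property tests)
oracle_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  total <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c <- v[f[i, 3], ]
    total <- total + (a[1] * (b[2] * c[3] - b[3] * c[2]) -
                      a[2] * (b[1] * c[3] - b[3] * c[1]) +
                      a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
  }
  total
}

# random well-behaved convex-ish test mesh: an icosphere squashed by a
# random positive-definite diagonal + rotation, plus a random translation
random_test_mesh <- function(seed, subdivisions = 2) {
  withr::with_seed(seed, {
    m <- stncoalign::icosphere(subdivisions)
    ax <- runif(3, 0.5, 3)
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    v <- sweep(m$vertices, 2, ax, "*") %*% (Rx %*% Ry %*% Rz)
    v <- sweep(v, 2, runif(3, -2, 2), "+")
    stncoalign::triangle_mesh(v, m$faces)
  })
}

# random tetrahedron (smallest valid watertight mesh)
random_tetrahedron <- function(seed) {
  withr::with_seed(seed, {
    repeat {
      v <- matrix(runif(12, -1, 1), 4, 3)
      vol <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) / 6
      if (abs(vol) > 0.05) break
    }
    f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
    m <- stncoalign::triangle_mesh(v, f)
    if (stncoalign::mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
    m
  })
}
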