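#' Unit icosphere mesh
#'
#' Geodesic sphere from repeated midpoint subdivision of an icosahedron,
#' vertices projected to the unit sphere; watertight and outward-oriented.
#'
#' @param subdivisions number of subdivision rounds (0 = icosahedron;
#'   each round quadruples the face count).
#' @return A [triangle_mesh()] with `20 * 4^subdivisions` faces.
#' @export
icosphere <- function(subdivisions = 3) {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- !duplicated(key)
    ue <- e[uk, , drop = FALSE]
    mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- nrow(v) + match(key, key[uk])
    m12 <- midx[seq_len(nf)]
    m23 <- midx[nf + seq_len(nf)]
    m13 <- midx[2 * nf + seq_len(nf)]
    v <- rbind(v, mid)
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23),
               cbind(m12, m23, m13))
  }
  mesh <- triangle_mesh(v, f)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Generate a synthetic STN-like mesh
#'
#' Ellipsoid (optionally with a smooth seeded radial perturbation) standing
#' in for the imaging-derived STN.  The default semi-axes give a
#' mediolateral full extent of about 6 mm, matching the anatomical size of
#' the human STN; the shape is synthetic and carries no atlas information.
#' The perturbation keeps the surface star-shaped, so the mesh remains
#' watertight for any `irregularity < 1`.
#'
#' @param seed RNG seed (perturbation field).
#' @param semi_axes 3-vector of ellipsoid semi-axes in mm
#'   (default `c(3.0, 5.5, 2.5)`).
#' @param irregularity relative amplitude of the smooth radial perturbation
#'   in `[0, 1)`; 0 gives an exact (triangulated) ellipsoid.
#' @param subdivisions icosphere subdivision level (default 4; volume then
#'   within ~0.2% of the analytic ellipsoid).
#' @param center mesh centre (mm).
#' @return A watertight [triangle_mesh()].
#' @export
generate_stn_mesh <- function(seed = 1, semi_axes = c(3.0, 5.5, 2.5),
                              irregularity = 0, subdivisions = 4,
                              center = c(0, 0, 0)) {
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0), irregularity >= 0)
  if (irregularity >= 1) {
    stop("irregularity >= 1 can collapse the radius (self-intersection)")
  }
  sph <- icosphere(subdivisions)
  u <- sph$vertices                      # unit directions
  r <- rep(1, nrow(u))
  if (irregularity > 0) {
    g <- with_seed(seed, {
      n_bumps <- 6L
      d <- matrix(rnorm(3 * n_bumps), n_bumps, 3)
      d <- d / sqrt(rowSums(d^2))
      a <- runif(n_bumps, -1, 1)
      width2 <- 2 * 0.6^2
      field <- numeric(nrow(u))
      for (m in seq_len(n_bumps)) {
        dd <- sweep(u, 2, d[m, ], "-")
        field <- field + a[m] * exp(-rowSums(dd^2) / width2)
      }
      field / max(abs(field))
    })
    r <- 1 + irregularity * g
  }
  v <- u * r
  v <- sweep(v, 2, semi_axes, "*")
  v <- sweep(v, 2, as.numeric(center), "+")
  mesh <- triangle_mesh(v, sph$faces)
  rep_ <- validate_mesh(mesh)
  if (!rep_$ok) stop("generated mesh failed validation: ",
                     paste(rep_$problems, collapse = "; "))
  mesh
}

#' Ben-gun electrode configuration
#'
#' Cross ("Ben-gun") layout of up to five parallel microelectrodes: Central
#' on the planned trajectory and Anterior/Posterior/Medial/Lateral at
#' `spacing` mm in the plane perpendicular to it, advanced together in
#' `step` mm increments over `depth_span` about the target.
#'
#' @param spacing perpendicular channel spacing in mm (default 2).
#' @param step depth increment in mm (default 0.5).
#' @param depth_span length-2 span in signed mm about the target
#'   (default `c(-10, 5)`; negative is above the target).
#' @param n_channels 1..5 channels, taken in the order Central, Anterior,
#'   Medial, Lateral, Posterior.
#' @return A list of class `bengun_config`.
#' @export
bengun_config <- function(spacing = 2.0, step = 0.5, depth_span = c(-10, 5),
                          n_channels = 5L) {
  stopifnot(spacing > 0, step > 0, length(depth_span) == 2L,
            depth_span[1] < depth_span[2], n_channels >= 1, n_channels <= 5)
  structure(list(spacing = spacing, step = step,
                 depth_span = as.numeric(depth_span),
                 n_channels = as.integer(n_channels)),
            class = "bengun_config")
}

default_approach <- function() {
  d <- c(0.25, 0.45, -0.86)
  d / sqrt(sum(d^2))
}

# orthonormal in-plane frame (e1 ~ mediolateral, e2 ~ anteroposterior) for a
# given approach direction
bengun_frame <- function(direction) {
  u <- direction / sqrt(sum(direction^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Generate Ben-gun trajectories and recording positions
#'
#' @param config a [bengun_config()].
#' @param target 3-vector planned target (depth 0) in mm.
#' @param approach_direction 3-vector advancement direction (normalised
#'   with a warning if not unit length).  The default is a typical
#'   double-oblique approach, about 25 degrees lateral and 30 degrees
#'   anterior from the vertical.
#' @return List with `trajectories` (named list of [trajectory()]) and
#'   `sites` (data.frame `trajectory_id`, `depth_mm`, `x`, `y`, `z` of every
#'   recording position).
#' @export
generate_bengun <- function(config = bengun_config(), target = c(0, 0, 0),
                            approach_direction = default_approach()) {
  stopifnot(inherits(config, "bengun_config"))
  target <- as.numeric(target)
  approach_direction <- as.numeric(approach_direction)
  nrm <- sqrt(sum(approach_direction^2))
  if (abs(nrm - 1) > 1e-7) {
    warning("approach_direction is not unit length; normalising")
  }
  fr <- bengun_frame(approach_direction)
  s <- config$spacing
  offsets <- list(Central = c(0, 0),
                  Anterior = c(0, s),
                  Medial = c(-s, 0),
                  Lateral = c(s, 0),
                  Posterior = c(0, -s))
  offsets <- offsets[seq_len(config$n_channels)]
  depths <- seq(config$depth_span[1], config$depth_span[2], by = config$step)
  trajectories <- list()
  rows <- list()
  for (ch in names(offsets)) {
    off3 <- offsets[[ch]][1] * fr$e1 + offsets[[ch]][2] * fr$e2
    anchor <- target + off3
    trajectories[[ch]] <- trajectory(anchor, fr$u, config$depth_span)
    pos <- sweep(outer(depths, fr$u), 2, anchor, "+")
    rows[[ch]] <- data.frame(trajectory_id = ch, depth_mm = depths,
                             x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  list(trajectories = trajectories, sites = do.call(rbind, rows))
}

#' Simulate raw MER segments for recording sites
#'
#' Band-limited Gaussian background whose in-band RMS equals
#' `outside_sigma` outside the mesh and `inside_sigma` inside, plus (inside
#' only) Poisson spike events with a biexponential waveform for cosmetic
#' realism.  The white noise is pre-compensated for the band-pass power
#' loss, so the *filtered* segment RMS matches the requested sigma.
#'
#' @param sites a sites data.frame (`trajectory_id`, `depth_mm`, `x`, `y`,
#'   `z`), e.g. from [generate_bengun()].
#' @param mesh the ground-truth [triangle_mesh()] determining inside/outside.
#' @param inside_sigma,outside_sigma target in-band RMS in microvolts
#'   (defaults 25 and 10; must satisfy `inside_sigma > outside_sigma > 0`).
#' @param duration segment length in seconds (default 10).
#' @param rate sampling rate in Hz (default 24000; must exceed twice the
#'   upper band edge).
#' @param seed RNG seed; channel/depth streams are derived from it.
#' @param band band-pass edges in Hz (default `c(500, 5000)`).
#' @param spike_rate Poisson spike rate inside the mesh (Hz, default 40).
#' @return List of [mer_segment()] in the row order of `sites`.
#' @export
simulate_mer_raw <- function(sites, mesh, inside_sigma = 25, outside_sigma = 10,
                             duration = 10, rate = 24000, seed = 1,
                             band = c(500, 5000), spike_rate = 40) {
  stopifnot(inside_sigma > outside_sigma, outside_sigma > 0, duration > 0)
  if (rate <= 2 * band[2]) {
    stop("sampling rate must exceed twice the upper band edge")
  }
  inside <- point_in_mesh(as.matrix(sites[, c("x", "y", "z")]), mesh)
  n <- round(duration * rate)
  gain <- bandpass_noise_gain(rate, band[1], band[2])
  # biexponential spike waveform (sharp rise, slower decay), peak ~2 sigma
  tw <- seq(0, 0.004, by = 1 / rate)
  wave <- exp(-tw / 0.0005) - exp(-tw / 0.0002)
  wave <- wave / max(wave)
  with_seed(seed, {
    lapply(seq_len(nrow(sites)), function(i) {
      sigma <- if (inside[i]) inside_sigma else outside_sigma
      x <- rnorm(n, sd = sigma / gain)
      if (inside[i] && spike_rate > 0) {
        n_spikes <- rpois(1, spike_rate * duration)
        if (n_spikes > 0) {
          at <- sample.int(n - length(wave), n_spikes, replace = TRUE)
          amp <- 2 * sigma * runif(n_spikes, 0.6, 1.4) *
            sign(runif(n_spikes) - 0.5)
          for (k in seq_len(n_spikes)) {
            idx <- at[k] + seq_along(wave) - 1L
            x[idx] <- x[idx] + amp[k] * wave
          }
        }
      }
      x <- bandpass_filter(x, rate, band[1], band[2])
      mer_segment(x, rate, sites$depth_mm[i], sites$trajectory_id[i])
    })
  })
}

#' Generate a complete synthetic co-alignment scene
#'
#' Composes an STN-like mesh, Ben-gun trajectories, simulated NRMS values
#' and ground-truth labels with an injected, recoverable perturbation.
#' Labels are computed from the *unperturbed* geometry against the mesh
#' scaled by `true_scale` (the electrophysiological STN), then the reported
#' site positions are translated by `true_shift` (stereotactic error /
#' brain shift).  Consequently, for a noise-free scene the alignment cost
#' is exactly 0 at `(true_shift, true_scale)`, which is what co-alignment
#' must recover.
#'
#' @param seed scene seed; the whole scene is a pure function of its
#'   arguments and this seed.
#' @param true_shift injected 3-vector shift in mm (warn if its norm
#'   exceeds 3).
#' @param true_scale injected isotropic scale (warn if outside
#'   `[0.8, 1.2]`).
#' @param label_noise_rate probability of flipping each site label.
#' @param bengun a [bengun_config()].
#' @param target planned target point (mm).
#' @param approach_direction advancement direction.
#' @param semi_axes,irregularity,subdivisions mesh parameters, see
#'   [generate_stn_mesh()].
#' @param mesh_offset STN centre relative to the target (mm); the default
#'   places the nucleus slightly anterior/lateral to the planned target.
#' @param inside_nrms,outside_nrms,nrms_sd NRMS emission model: Gaussian
#'   per-depth NRMS around these means (defaults 3, 1, 0.1), driven by the
#'   true membership.
#' @return An object of class `synthetic_scene`: `mesh` (imaging mesh),
#'   `trajectories` and `sites` (observed, i.e. perturbed, geometry with
#'   labels), `nrms` (list of [nrms_sequence()] per channel), `true_shift`,
#'   `true_scale`, `label_noise_rate`, `seed` and `scale_center`.
#' @export
make_scene <- function(seed = 1, true_shift = c(0, 0, 0), true_scale = 1,
                       label_noise_rate = 0, bengun = bengun_config(),
                       target = c(0, 0, 0),
                       approach_direction = default_approach(),
                       semi_axes = c(3.0, 5.5, 2.5), irregularity = 0.05,
                       subdivisions = 3, mesh_offset = c(0.5, 1.0, -0.5),
                       inside_nrms = 3.0, outside_nrms = 1.0, nrms_sd = 0.1) {
  true_shift <- as.numeric(true_shift)
  stopifnot(length(true_shift) == 3L)
  if (sqrt(sum(true_shift^2)) > 3 + 1e-9) {
    warning("||true_shift|| exceeds the 3 mm clinical bound; recovery is not guaranteed")
  }
  if (true_scale < 0.8 || true_scale > 1.2) {
    warning("true_scale outside [0.8, 1.2]; recovery is not guaranteed")
  }
  mesh <- generate_stn_mesh(seed, semi_axes, irregularity, subdivisions,
                            center = as.numeric(target) + as.numeric(mesh_offset))
  centroid <- mesh_centroid(mesh)
  geo <- generate_bengun(bengun, target, approach_direction)
  true_pos <- as.matrix(geo$sites[, c("x", "y", "z")])
  truth_mesh <- scale_mesh(mesh, true_scale, centroid)
  membership <- as.integer(point_in_mesh(true_pos, truth_mesh))

  labels <- membership
  nrms_tab <- NULL
  with_seed(seed + 1L, {
    if (label_noise_rate > 0) {
      flip <- runif(length(labels)) < label_noise_rate
      labels[flip] <- 1L - labels[flip]
    }
    raw <- rnorm(length(membership),
                 mean = ifelse(membership == 1L, inside_nrms, outside_nrms),
                 sd = nrms_sd)
    nrms_tab <- pmax(raw, 0.05)
  })

  sites <- geo$sites
  sites$x <- sites$x + true_shift[1]
  sites$y <- sites$y + true_shift[2]
  sites$z <- sites$z + true_shift[3]
  sites$label <- labels
  sites <- recording_sites(sites)

  trajectories <- lapply(geo$trajectories, function(tr) {
    tr$anchor <- tr$anchor + true_shift
    tr
  })
  names(trajectories) <- names(geo$trajectories)

  nrms <- lapply(split(seq_len(nrow(sites)), sites$trajectory_id), function(idx) {
    idx <- idx[order(sites$depth_mm[idx])]
    nrms_sequence(sites$trajectory_id[idx[1]], sites$depth_mm[idx],
                  nrms_tab[idx])
  })

  structure(list(mesh = mesh, trajectories = trajectories, sites = sites,
                 nrms = nrms, membership = membership,
                 true_shift = true_shift, true_scale = true_scale,
                 label_noise_rate = label_noise_rate, seed = seed,
                 scale_center = centroid,
                 params = list(bengun = bengun, target = target,
                               approach_direction = approach_direction,
                               semi_axes = semi_axes,
                               irregularity = irregularity,
                               subdivisions = subdivisions,
                               mesh_offset = mesh_offset,
                               inside_nrms = inside_nrms,
                               outside_nrms = outside_nrms,
                               nrms_sd = nrms_sd)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene (seed %d): %d sites on %d trajectories, %d STN-labelled\n",
              x$seed, nrow(x$sites), length(x$trajectories), sum(x$sites$label)))
  cat(sprintf("  true shift (%.2f, %.2f, %.2f) mm, true scale %.3f, label noise %.2f\n",
              x$true_shift[1], x$true_shift[2], x$true_shift[3],
              x$true_scale, x$label_noise_rate))
  invisible(x)
}

#' Generate a separable NRMS training corpus
#'
#' Independent synthetic tracks for classifier development: each track has
#' one contiguous STN run with NRMS around `inside_mean` inside and
#' `outside_mean` outside (Gaussian, sd `sd`), clipped to stay positive.
#' With the defaults the two classes are well separated, so a competent
#' classifier should approach perfect per-depth accuracy.
#'
#' @param n_tracks number of tracks.
#' @param seed RNG seed.
#' @param n_depths depths per track (default 31, i.e. -10..+5 mm at 0.5).
#' @param inside_mean,outside_mean,sd NRMS emission parameters
#'   (defaults 3, 1, 0.1).
#' @param run_range length-2 range of the STN run length in depths
#'   (default `c(6, 14)`).
#' @return List of tracks, each a list with `nrms` ([nrms_sequence()]) and
#'   `labels` ([depth_labels()]).
#' @export
make_classifier_corpus <- function(n_tracks = 200, seed = 1, n_depths = 31,
                                   inside_mean = 3.0, outside_mean = 1.0,
                                   sd = 0.1, run_range = c(6, 14)) {
  stopifnot(n_tracks >= 1, n_depths >= 3, run_range[1] >= 1,
            run_range[2] <= n_depths, run_range[1] <= run_range[2])
  depths <- seq(-10, by = 0.5, length.out = n_depths)
  with_seed(seed, {
    lapply(seq_len(n_tracks), function(i) {
      len <- sample(run_range[1]:run_range[2], 1)
      start <- sample.int(n_depths - len + 1L, 1)
      lab <- integer(n_depths)
      lab[start:(start + len - 1L)] <- 1L
      val <- rnorm(n_depths, ifelse(lab == 1L, inside_mean, outside_mean), sd)
      id <- sprintf("track%03d", i)
      list(nrms = nrms_sequence(id, depths, pmax(val, 0.05)),
           labels = depth_labels(id, depths, lab))
    })
  })
}
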