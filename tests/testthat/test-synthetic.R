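test_that("generate_stn_mesh: analytic volume, determinism, stated extent", {
  m <- generate_stn_mesh(seed = 1, irregularity = 0, subdivisions = 4)
  expect_true(validate_mesh(m)$ok)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 3 * 5.5 * 2.5, tolerance = 0.01)
  # mediolateral (x) full extent of the default nucleus is 6 mm
  expect_equal(diff(range(m$vertices[, 1])), 6.0, tolerance = 0.1)

  m2 <- generate_stn_mesh(seed = 42, irregularity = 0.1, subdivisions = 3)
  m3 <- generate_stn_mesh(seed = 42, irregularity = 0.1, subdivisions = 3)
  expect_identical(m2$vertices, m3$vertices)
  expect_true(validate_mesh(m2)$ok)
  expect_error(generate_stn_mesh(seed = 1, irregularity = 1.2), "irregularity")
})

test_that("generate_bengun reproduces the cross geometry exactly", {
  geo <- generate_bengun(bengun_config(), target = c(10, -5, 2))
  expect_named(geo$trajectories,
               c("Central", "Anterior", "Medial", "Lateral", "Posterior"))
  ctr <- geo$trajectories$Central
  # perpendicular distance from Central to each peripheral trajectory = 2 mm
  for (ch in c("Anterior", "Medial", "Lateral", "Posterior")) {
    expect_equal(lateral_distance(ctr, geo$trajectories[[ch]]), 2.0,
                 tolerance = 1e-12)
  }
  # adjacent arms 2*sqrt(2) apart, opposite arms 4 apart
  expect_equal(lateral_distance(geo$trajectories$Anterior,
                                geo$trajectories$Medial), 2 * sqrt(2),
               tolerance = 1e-12)
  expect_equal(lateral_distance(geo$trajectories$Medial,
                                geo$trajectories$Lateral), 4,
               tolerance = 1e-12)
  # 0.5 mm steps over [-10, 5] -> 31 depths per channel
  expect_equal(nrow(geo$sites), 5 * 31)
  expect_equal(sum(geo$sites$trajectory_id == "Central"), 31)
  # all channels share the direction; depth 0 is the target for Central
  at0 <- geo$sites[geo$sites$trajectory_id == "Central" & geo$sites$depth_mm == 0, ]
  expect_equal(as.numeric(at0[, c("x", "y", "z")]), c(10, -5, 2), tolerance = 1e-12)
  expect_warning(generate_bengun(approach_direction = c(0, 0, -2)), "unit")
})

test_that("make_scene composes a consistent, seeded, recoverable world", {
  sc <- make_scene(seed = 4)
  expect_equal(alignment_cost(sc$sites, sc$mesh, c(0, 0, 0), 1, sc$scale_center), 0)

  sc2 <- make_scene(seed = 31, true_shift = c(1.5, -1, 0.5), true_scale = 0.9)
  expect_equal(alignment_cost(sc2$sites, sc2$mesh, sc2$true_shift,
                              sc2$true_scale, sc2$scale_center), 0)
  # flipping every label must strictly worsen the cost at the true parameters
  flipped <- sc2$sites
  flipped$label <- 1L - flipped$label
  expect_gt(alignment_cost(flipped, sc2$mesh, sc2$true_shift, sc2$true_scale,
                           sc2$scale_center), 0)

  # bit-exact regeneration from the same seed
  sc2b <- make_scene(seed = 31, true_shift = c(1.5, -1, 0.5), true_scale = 0.9)
  expect_identical(sc2$mesh$vertices, sc2b$mesh$vertices)
  expect_identical(sc2$sites, sc2b$sites)
  expect_identical(sc2$nrms$Central$nrms, sc2b$nrms$Central$nrms)

  expect_warning(make_scene(seed = 1, true_shift = c(4, 0, 0)), "3 mm")
  expect_warning(make_scene(seed = 1, true_scale = 1.4), "0.8")
})

test_that("label noise flips the binomially expected number of labels", {
  flips <- vapply(1:40, function(k) {
    clean <- make_scene(seed = 200 + k)
    noisy <- make_scene(seed = 200 + k, label_noise_rate = 0.1)
    sum(clean$sites$label != noisy$sites$label)
  }, numeric(1))
  n <- 155
  # mean flip count within the 99% CI of Binomial(155 * 40, 0.1) scaled back
  expect_lt(abs(mean(flips) - n * 0.1),
            2.58 * sqrt(n * 0.1 * 0.9 / 40))
  # noise increases the minimum achievable cost in expectation
  clean_costs <- vapply(1:10, function(k) {
    sc <- make_scene(seed = 300 + k)
    alignment_cost(sc$sites, sc$mesh, c(0, 0, 0), 1, sc$scale_center)
  }, numeric(1))
  noisy_costs <- vapply(1:10, function(k) {
    sc <- make_scene(seed = 300 + k, label_noise_rate = 0.15)
    alignment_cost(sc$sites, sc$mesh, c(0, 0, 0), 1, sc$scale_center)
  }, numeric(1))
  expect_gt(mean(noisy_costs), mean(clean_costs))
})

test_that("simulate_mer_raw produces calibrated, seeded, band-limited signals", {
  sc <- make_scene(seed = 9)
  # one deep-inside and one far-outside site, short segments for speed
  inside_idx <- which(sc$membership == 1)
  d <- distance_to_surface(as.matrix(sc$sites[, c("x", "y", "z")]), sc$mesh)
  pick_in <- inside_idx[which.max(d[inside_idx])]
  pick_out <- which.max(d * (sc$membership == 0))
  sites <- sc$sites[c(pick_in, pick_out), ]
  # undo the observed-position shift so membership matches the mesh
  segs <- simulate_mer_raw(sites, sc$mesh, duration = 2, seed = 5)
  rms_in <- compute_rms(segs[[1]])
  rms_out <- compute_rms(segs[[2]])
  expect_lt(abs(rms_in - 25) / 25, 0.05)
  expect_lt(abs(rms_out - 10) / 10, 0.05)

  segs2 <- simulate_mer_raw(sites, sc$mesh, duration = 2, seed = 5)
  expect_identical(segs[[1]]$samples, segs2[[1]]$samples)

  expect_error(simulate_mer_raw(sites, sc$mesh, rate = 9000), "twice")
  expect_error(simulate_mer_raw(sites, sc$mesh, inside_sigma = 5,
                                outside_sigma = 10), "inside_sigma")
})

test_that("NRMS computed from simulated raw segments matches the scene model", {
  sc <- make_scene(seed = 14)
  central <- sc$sites[sc$sites$trajectory_id == "Central", ]
  # move sites back to true geometry so raw simulation sees true membership
  segs <- simulate_mer_raw(central, sc$mesh, duration = 0.5, seed = 2,
                           spike_rate = 0)
  nr <- compute_nrms(segs, n_baseline = 5)
  lab <- sc$membership[sc$sites$trajectory_id == "Central"]
  # outside depths sit near 1, inside near 2.5 (= 25/10)
  expect_lt(max(abs(nr$nrms[lab == 0] - 1)), 0.15)
  expect_lt(max(abs(nr$nrms[lab == 1] - 2.5)), 0.3)
})
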