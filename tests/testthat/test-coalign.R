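test_that("alignment_cost closed forms: agreement, forced 0.5, errors", {
  cube <- unit_cube_mesh(edge = 2)  # [-1, 1]^3
  sites <- recording_sites(data.frame(
    trajectory_id = "Central", depth_mm = 1:4,
    x = c(0, 0.5, 3, 0), y = c(0, 0, 0, 5), z = 0,
    label = c(1, 1, 0, 0)))
  expect_equal(alignment_cost(sites, cube), 0)

  # one disagreeing site at surface distance 2 (outside point labelled STN)
  sites2 <- sites
  sites2$label[3] <- 1L
  expect_equal(alignment_cost(sites2, cube), 0.5)  # (1/4) * 2.0

  expect_error(alignment_cost(sites[0, ], cube), "empty")
  expect_error(alignment_cost(sites, cube, alpha = 0), "positive")
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(alignment_cost(sites, open_mesh), "invalid mesh")
})

test_that("alignment_cost equals an independent per-site loop on random scenes", {
  # oracle built only from the exported point primitives
  cost_oracle <- function(sites, mesh, s, alpha, ctr) {
    scaled <- scale_mesh(mesh, alpha, ctr)
    total <- 0
    for (i in seq_len(nrow(sites))) {
      p <- c(sites$x[i], sites$y[i], sites$z[i]) - s
      y_star <- point_in_mesh(p, scaled)
      if (as.integer(y_star) != sites$label[i]) {
        total <- total + distance_to_surface(p, scaled)
      }
    }
    total / nrow(sites)
  }
  for (k in 1:20) {
    sc <- make_scene(seed = 600 + k,
                     true_shift = withr::with_seed(k, runif(3, -1.5, 1.5)),
                     true_scale = withr::with_seed(k + 99, runif(1, 0.85, 1.15)),
                     label_noise_rate = 0.1)
    ctr <- sc$scale_center
    par <- withr::with_seed(700 + k, c(runif(3, -2, 2), runif(1, 0.8, 1.2)))
    got <- alignment_cost(sc$sites, sc$mesh, par[1:3], par[4], ctr)
    want <- cost_oracle(sc$sites, sc$mesh, par[1:3], par[4], ctr)
    expect_equal(got, want, tolerance = 1e-13)
    expect_gte(got, 0)
  }
})

test_that("cost is invariant under joint translation of sites and mesh", {
  sc <- make_scene(seed = 55, true_shift = c(1, -0.5, 0.3))
  shift <- c(7.5, -12.25, 3.125)
  sites2 <- sc$sites
  sites2$x <- sites2$x + shift[1]
  sites2$y <- sites2$y + shift[2]
  sites2$z <- sites2$z + shift[3]
  mesh2 <- triangle_mesh(sweep(sc$mesh$vertices, 2, shift, "+"), sc$mesh$faces)
  for (par in list(c(0, 0, 0, 1), c(1.5, -1, 0.5, 1.1))) {
    expect_equal(
      alignment_cost(sites2, mesh2, par[1:3], par[4], sc$scale_center + shift),
      alignment_cost(sc$sites, sc$mesh, par[1:3], par[4], sc$scale_center),
      tolerance = 1e-12)
  }
})

test_that("coalign on a consistent scene returns the identity", {
  sc <- make_scene(seed = 3)  # no perturbation, no noise
  res <- coalign(sc$sites, sc$mesh)
  expect_lt(sqrt(sum(res$shift^2)), 0.3)
  expect_lt(abs(res$scale - 1), 0.03)
  expect_equal(res$cost_final, 0)
  expect_lte(res$cost_final, res$cost_initial)
})

test_that("coalign recovers an injected perturbation (small batch)", {
  # 6 seeded scenes as a fast stand-in; the 50-scene version lives in the
  # acceptance suite
  errs <- numeric(6)
  for (i in 1:6) {
    set.seed(400 + i)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    s_true <- d * runif(1, 0.5, 2.5)
    a_true <- runif(1, 0.85, 1.15)
    sc <- make_scene(seed = 400 + i, true_shift = s_true, true_scale = a_true)
    res <- coalign(sc$sites, sc$mesh, multi_start = TRUE)
    errs[i] <- sqrt(sum((res$shift - s_true)^2))
    expect_true(sqrt(sum(res$shift^2)) <= 3 + 1e-9)
    expect_gte(res$scale, 0.8)
    expect_lte(res$scale, 1.2)
    expect_lte(res$cost_final, res$cost_initial)
  }
  expect_gte(mean(errs <= 0.5), 0.5)
  expect_lte(median(errs), 0.5)
})

test_that("coalign respects degenerate bounds (scale-only optimisation)", {
  sc <- make_scene(seed = 8, true_scale = 1.1)
  res <- coalign(sc$sites, sc$mesh,
                 coalignment_bounds(max_shift_norm = 1e-9,
                                    scale_range = c(0.8, 1.2)))
  expect_equal(res$shift, c(0, 0, 0), tolerance = 1e-6)
  expect_lt(abs(res$scale - 1.1), 0.05)
})

test_that("single-class scenes warn", {
  sc <- make_scene(seed = 5)
  sites <- sc$sites
  sites$label[] <- 1L
  expect_warning(coalign(sites, sc$mesh, maxeval = 300), "single class")
})

test_that("apply_coalignment is consistent and invertible", {
  sc <- make_scene(seed = 12, true_shift = c(1, 0.5, -0.8), true_scale = 0.9,
                   label_noise_rate = 0.05)
  res <- coalign(sc$sites, sc$mesh)

  # identity result leaves the scene unchanged
  ident <- list(shift = c(0, 0, 0), scale = 1, scale_center = sc$scale_center)
  same <- apply_coalignment(sc$sites, sc$mesh, ident, sc$trajectories)
  expect_equal(same$sites$x, sc$sites$x)
  expect_equal(same$mesh$vertices, sc$mesh$vertices)

  # transformed-scene cost at the identity equals cost_final
  tf <- apply_coalignment(sc$sites, sc$mesh, res, sc$trajectories)
  expect_equal(alignment_cost(tf$sites, tf$mesh, c(0, 0, 0), 1, res$scale_center),
               res$cost_final, tolerance = 1e-12)

  # inverse transform restores the original coordinates
  inv <- list(shift = -res$shift, scale = 1 / res$scale,
              scale_center = res$scale_center)
  back <- apply_coalignment(tf$sites, tf$mesh, inv, tf$trajectories)
  expect_equal(back$sites$x, sc$sites$x, tolerance = 1e-12)
  expect_equal(back$mesh$vertices, sc$mesh$vertices, tolerance = 1e-12)
  expect_equal(back$trajectories$Central$anchor, sc$trajectories$Central$anchor,
               tolerance = 1e-12)
})

test_that("powell_minimize solves smooth and non-smooth reference problems", {
  # convex quadratic with known minimiser inside the box
  f1 <- function(p) sum((p - c(0.5, -0.25, 1))^2) + 2
  r1 <- powell_minimize(f1, c(0, 0, 0), rep(-2, 3), rep(2, 3))
  expect_equal(r1$par, c(0.5, -0.25, 1), tolerance = 1e-3)
  expect_true(r1$converged)

  # minimiser pinned at the box boundary
  f2 <- function(p) sum(p^2)
  r2 <- powell_minimize(f2, c(1.5, 1.5), c(1, -2), c(2, 2))
  expect_equal(r2$par, c(1, 0), tolerance = 1e-3)

  # non-differentiable: sum of absolute values
  f3 <- function(p) sum(abs(p - c(0.3, -0.7)))
  r3 <- powell_minimize(f3, c(1, 1), c(-2, -2), c(2, 2))
  expect_equal(r3$par, c(0.3, -0.7), tolerance = 1e-3)

  # Rosenbrock (needs the direction-replacement heuristic)
  f4 <- function(p) 100 * (p[2] - p[1]^2)^2 + (1 - p[1])^2
  r4 <- powell_minimize(f4, c(-1.2, 1), c(-5, -5), c(5, 5), maxiter = 500)
  expect_lt(f4(r4$par), 1e-4)
})
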