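test_that("validate_mesh flags the documented invariant violations", {
  cube <- unit_cube_mesh()
  rep_ok <- validate_mesh(cube)
  expect_true(rep_ok$watertight)
  expect_true(rep_ok$ok)
  expect_length(rep_ok$problems, 0)

  open_cube <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  rep_open <- validate_mesh(open_cube)
  expect_false(rep_open$watertight)
  expect_match(paste(rep_open$problems, collapse = " "), "watertight")

  bad_idx <- triangle_mesh(cube$vertices, rbind(cube$faces, c(1, 2, 99)))
  expect_false(validate_mesh(bad_idx)$indices_valid)

  degen <- triangle_mesh(cube$vertices, rbind(cube$faces, c(1, 1, 2)))
  expect_false(validate_mesh(degen)$faces_distinct)

  tiny <- triangle_mesh(cube$vertices[1:3, ], matrix(c(1, 2, 3), 1))
  expect_false(validate_mesh(tiny)$size_ok)
})

test_that("point_in_mesh handles the closed-form cube cases", {
  cube <- unit_cube_mesh()
  expect_true(point_in_mesh(c(0, 0, 0), cube))
  expect_false(point_in_mesh(c(10, 0, 0), cube))
  # boundary tolerance: a point on a face counts as inside
  expect_true(point_in_mesh(c(0.5, 0, 0), cube))
  expect_error(point_in_mesh(c(0, 0, 0), triangle_mesh(cube$vertices, cube$faces[-1, ])),
               "invalid mesh")
})

test_that("point_in_mesh agrees with winding and independent-parity oracles", {
  for (seed in 1:6) {
    mesh <- if (seed %% 2 == 0) random_test_mesh(seed) else random_tetrahedron(seed)
    bb <- apply(mesh$vertices, 2, range)
    pts <- withr::with_seed(100 + seed, {
      cbind(runif(150, bb[1, 1], bb[2, 1]),
            runif(150, bb[1, 2], bb[2, 2]),
            runif(150, bb[1, 3], bb[2, 3]))
    })
    got <- point_in_mesh(pts, mesh)
    wind <- vapply(seq_len(nrow(pts)), function(i) oracle_inside(pts[i, ], mesh), logical(1))
    expect_identical(got, wind)
    parity <- vapply(seq_len(nrow(pts)), function(i) {
      oracle_inside_parity(pts[i, ], mesh, dir = c(0.31, -0.52, 0.88))
    }, logical(1))
    expect_identical(got, parity)
  }
})

test_that("distance_to_surface matches closed forms and the brute-force oracle", {
  cube <- unit_cube_mesh()
  expect_equal(distance_to_surface(c(0, 0, 0), cube), 0.5)
  expect_equal(distance_to_surface(c(2, 0, 0), cube), 1.5)
  expect_equal(distance_to_surface(c(0.5, 0, 0), cube), 0)

  for (seed in 1:4) {
    mesh <- random_test_mesh(seed)
    pts <- withr::with_seed(200 + seed, matrix(runif(90, -4, 4), ncol = 3))
    got <- distance_to_surface(pts, mesh)
    want <- vapply(seq_len(nrow(pts)), function(i) oracle_distance(pts[i, ], mesh),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(max(abs(got - want)) <= 1e-9)
  }
})

test_that("scale_mesh scales volume by alpha^3 and inverts exactly", {
  cube <- unit_cube_mesh()
  expect_equal(scale_mesh(cube, 1)$vertices, cube$vertices)
  big <- scale_mesh(cube, 1.2)
  expect_equal(mesh_volume(big), 1.728, tolerance = 1e-12)
  expect_equal(diff(range(big$vertices[, 1])), 1.2)

  for (seed in 1:5) {
    mesh <- random_test_mesh(seed)
    alpha <- withr::with_seed(300 + seed, runif(1, 0.8, 1.2))
    scaled <- scale_mesh(mesh, alpha)
    expect_equal(mesh_volume(scaled) / mesh_volume(mesh), alpha^3,
                 tolerance = 1e-9)
    back <- scale_mesh(scaled, 1 / alpha, mesh_centroid(mesh))
    expect_true(max(abs(back$vertices - mesh$vertices)) < 1e-12)
  }
  expect_error(scale_mesh(cube, 0), "positive")
  expect_error(scale_mesh(cube, -1), "positive")
})

test_that("mesh_centroid: symmetry, translation equivariance, tetrahedron closed form", {
  expect_equal(mesh_centroid(unit_cube_mesh()), c(0, 0, 0))
  expect_equal(mesh_centroid(unit_cube_mesh(center = c(1, 2, 3))), c(1, 2, 3))
  for (seed in 1:5) {
    tet <- random_tetrahedron(seed)
    expect_equal(mesh_centroid(tet), colMeans(tet$vertices), tolerance = 1e-12)
  }
})

test_that("inclusion and distance obey the scaling covariance identity", {
  mesh <- random_test_mesh(7)
  ctr <- mesh_centroid(mesh)
  pts <- withr::with_seed(41, matrix(runif(60, -3, 3), ncol = 3))
  for (alpha in c(0.8, 1.07, 1.2)) {
    scaled <- scale_mesh(mesh, alpha, ctr)
    lhs <- distance_to_surface(pts, scaled)
    pre <- sweep(sweep(pts, 2, ctr, "-") / alpha, 2, ctr, "+")
    rhs <- alpha * distance_to_surface(pre, mesh)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("inclusion is invariant under joint rigid translation", {
  mesh <- random_test_mesh(9)
  pts <- withr::with_seed(42, matrix(runif(60, -3, 3), ncol = 3))
  base <- point_in_mesh(pts, mesh)
  shift <- c(11.5, -3.25, 7.75)
  moved <- triangle_mesh(sweep(mesh$vertices, 2, shift, "+"), mesh$faces)
  expect_identical(point_in_mesh(sweep(pts, 2, shift, "+"), moved), base)
})

test_that("mesh I/O round-trips across STL (ascii + binary), PLY and VTK", {
  mesh <- random_test_mesh(11)
  tdir <- withr::local_tempdir()
  p_stl <- file.path(tdir, "m.stl")
  p_stlb <- file.path(tdir, "mb.stl")
  p_ply <- file.path(tdir, "m.ply")
  p_vtk <- file.path(tdir, "m.vtk")

  write_mesh(mesh, p_stl)
  back <- read_mesh(p_stl)
  expect_equal(mesh_volume(back), mesh_volume(mesh), tolerance = 1e-6)
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))

  write_mesh(mesh, p_stlb, binary = TRUE)
  backb <- read_mesh(p_stlb)
  expect_equal(mesh_volume(backb), mesh_volume(mesh), tolerance = 1e-4)

  write_mesh(mesh, p_ply)
  backp <- read_mesh(p_ply)
  expect_true(max(abs(backp$vertices - mesh$vertices)) < 1e-6)
  expect_identical(backp$faces, mesh$faces)

  write_mesh(mesh, p_vtk)
  backv <- read_mesh(p_vtk)
  expect_true(max(abs(backv$vertices - mesh$vertices)) < 1e-6)
  expect_identical(backv$faces, mesh$faces)

  # cross-format chain STL -> PLY -> STL preserves geometry
  write_mesh(back, p_ply)
  chain <- read_mesh(p_ply)
  write_mesh(chain, p_stl)
  final <- read_mesh(p_stl)
  expect_equal(mesh_volume(final), mesh_volume(mesh), tolerance = 1e-6)
})
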