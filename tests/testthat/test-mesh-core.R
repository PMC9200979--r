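# Mesh data model, I/O and elementary closed-surface geometry.

test_that("OBJ round trip preserves geometry and triangulates quads", {
  tmp <- withr::local_tempfile(fileext = ".obj")
  # unit cube written as 6 quads
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  quads <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
                 c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  writeLines(c(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d %d", quads[, 1], quads[, 2], quads[, 3],
                       quads[, 4])), tmp)
  m <- read_mesh(tmp)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)   # fan triangulation doubles the quads
  expect_true(is_watertight(m))
  expect_equal(abs(signed_volume(m)), 1, tolerance = 1e-9)

  m2 <- unit_cube_mesh()
  write_mesh(m2, tmp)
  m3 <- read_mesh(tmp)
  expect_equal(signed_volume(m3), 1, tolerance = 1e-6)
  expect_equal(nrow(m3$vertices), nrow(m2$vertices))
})

test_that("PLY round trip reproduces the cube", {
  tmp <- withr::local_tempfile(fileext = ".ply")
  write_mesh(unit_cube_mesh(), tmp)
  m <- read_mesh(tmp)
  expect_equal(signed_volume(m), 1, tolerance = 1e-6)
  expect_equal(surface_area(m), 6, tolerance = 1e-6)
})

test_that("OBJ parser rejects 0-based face indices and empty files", {
  tmp <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 0 1 2"), tmp)
  expect_error(read_mesh(tmp), "1-based")
  writeLines(character(0), tmp)
  expect_error(read_mesh(tmp), "format error")
  expect_error(read_mesh(file.path(tempdir(), "nope_missing.obj")), "exist")
})

test_that("signed volume and area match analytic values", {
  expect_equal(signed_volume(unit_cube_mesh()), 1, tolerance = 1e-12)
  expect_equal(surface_area(unit_cube_mesh()), 6, tolerance = 1e-12)
  box <- box_mesh(c(12.5, 12.5, 34))   # the reference box dimensions
  expect_equal(signed_volume(box), 5312.5, tolerance = 1e-9)
  expect_equal(surface_area(box), 2012.5, tolerance = 1e-9)
  s <- icosphere_mesh(5, 3)
  expect_equal(signed_volume(s), 4 / 3 * pi * 125, tolerance = 0.01)
  expect_equal(surface_area(s), 4 * pi * 25, tolerance = 0.01)
  cyl <- cylinder_mesh(5, 10, n_around = 64)
  expect_equal(signed_volume(cyl), pi * 25 * 10, tolerance = 0.01)
  fr <- frustum_mesh(4, 1, 30, n_around = 64)
  expect_equal(signed_volume(fr), pi * 30 * (16 + 4 + 1) / 3, tolerance = 0.01)
})

test_that("signed volume honours unit_scale and orientation", {
  m <- unit_cube_mesh()
  m$unit_scale <- 2.5
  expect_equal(signed_volume(m), 2.5^3, tolerance = 1e-9)
  expect_equal(surface_area(m), 6 * 2.5^2, tolerance = 1e-9)
  flipped <- unit_cube_mesh()
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_lt(signed_volume(flipped), 0)
})

test_that("non-watertight meshes are rejected by signed_volume", {
  m <- unit_cube_mesh()
  m$faces <- m$faces[-1, ]
  expect_false(is_watertight(m))
  expect_error(signed_volume(m), "close_holes")
})

test_that("connected components partition faces by edge connectivity", {
  two <- merge_meshes(list(unit_cube_mesh(),
                           box_mesh(c(1, 1, 1), center = c(5, 5, 5))))
  comps <- connected_components(two)
  expect_length(comps, 2L)
  expect_equal(vapply(comps, function(m) nrow(m$faces), integer(1)),
               c(12L, 12L))
  expect_length(connected_components(unit_cube_mesh()), 1L)
  noisy <- add_floating_noise(unit_cube_mesh(), n = 50, size = 0.2, seed = 3)
  expect_length(connected_components(noisy), 51L)
})

test_that("plane_cut produces closed halves that conserve volume", {
  m <- unit_cube_mesh()
  pc <- plane_cut(m, mesh_plane(c(0.5, 0.5, 0.5), c(0, 0, 1)))
  expect_true(is_watertight(pc$below))
  expect_true(is_watertight(pc$above))
  expect_equal(signed_volume(pc$below), 0.5, tolerance = 1e-9)
  expect_equal(signed_volume(pc$above), 0.5, tolerance = 1e-9)

  s <- icosphere_mesh(5, 3)
  pc <- plane_cut(s, mesh_plane(c(0, 0, 2.5), c(0, 0, 1)))
  h <- 2.5
  cap_true <- pi * h^2 * (3 * 5 - h) / 3
  expect_equal(signed_volume(pc$above, check = FALSE), cap_true,
               tolerance = 0.02)
  expect_equal(signed_volume(pc$below, check = FALSE) +
                 signed_volume(pc$above, check = FALSE),
               signed_volume(s), tolerance = 1e-6)
})

test_that("plane_cut with a non-intersecting plane returns the input", {
  m <- unit_cube_mesh()
  pc <- plane_cut(m, mesh_plane(c(0, 0, 5), c(0, 0, 1)))
  expect_null(pc$above)
  expect_equal(signed_volume(pc$below), 1, tolerance = 1e-12)
})

test_that("plane_cut conserves volume for random planes through a crown", {
  set.seed(41)
  cr <- generate_crown(crown_spec(n_roots = 6, seed = 41), oracle_h = 0.5)
  m <- cr$crown_mesh
  v0 <- signed_volume(m)
  for (k in 1:4) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    p0 <- colMeans(m$vertices) + runif(3, -3, 3)
    pc <- plane_cut(m, mesh_plane(p0, n))
    vols <- sum(vapply(Filter(Negate(is.null), pc), signed_volume,
                       numeric(1), check = FALSE))
    expect_equal(vols, v0, tolerance = 1e-3)
  }
})

test_that("volume and area are rigid-motion invariant and scale correctly", {
  set.seed(7)
  m <- icosphere_mesh(3, 2)
  v0 <- signed_volume(m); a0 <- surface_area(m)
  for (k in 1:5) {
    mr <- transform_mesh(m, random_rotation(), rnorm(3, sd = 10))
    expect_equal(signed_volume(mr), v0, tolerance = 1e-6)
    expect_equal(surface_area(mr), a0, tolerance = 1e-6)
  }
  s <- 2.7
  ms <- scale_mesh(m, s)
  expect_equal(signed_volume(ms), v0 * s^3, tolerance = 1e-9)
  expect_equal(surface_area(ms), a0 * s^2, tolerance = 1e-9)
})

test_that("signed volume agrees with the voxel oracle on synthetic solids", {
  solids <- list(unit_cube_mesh(), box_mesh(c(3, 2, 5)), icosphere_mesh(4, 3),
                 cylinder_mesh(3, 8, n_around = 48),
                 frustum_mesh(3, 1, 12, n_around = 48))
  for (m in solids) {
    expect_equal(voxel_volume(m, h = 0.1), signed_volume(m), tolerance = 0.02)
  }
})
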