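# Whole-crown traits: split-half volume, diameter, cylinder soil volume,
# compactness, density, surface-to-volume ratio, aggregation.

test_that("split-half volume matches the direct volume on watertight input", {
  expect_equal(crown_volume_split(unit_cube_mesh()), 1, tolerance = 1e-9)
  cr <- generate_crown(crown_spec(n_roots = 6, seed = 21), oracle_h = 0.5)
  direct <- signed_volume(cr$crown_mesh)
  expect_equal(crown_volume_split(cr$crown_mesh), direct, tolerance = 0.005)
})

test_that("crown diameter is the maximum horizontal caliper", {
  cyl <- cylinder_mesh(10, 5, n_around = 128)
  expect_equal(crown_diameter(cyl), 20, tolerance = 0.01)
  # two opposite tips at x = -15 and x = +25: a deep z extent is ignored
  spikes <- triangle_mesh(
    rbind(c(-15, 0, 0), c(-14, 1, -40), c(-14, -1, -40),
          c(25, 0, 0), c(24, 1, -40), c(24, -1, -40)),
    rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(crown_diameter(spikes), 40, tolerance = 1e-9)
  # brute-force oracle over all projected vertex pairs
  cr <- generate_crown(crown_spec(n_roots = 5, seed = 22), oracle_h = 0.5)
  p <- cr$crown_mesh$vertices[, 1:2]
  brute <- max(dist(p))
  expect_equal(crown_diameter(cr$crown_mesh), brute, tolerance = 1e-9)
})

test_that("cylinder soil volume is the minimal vertical enclosing cylinder", {
  cyl <- cylinder_mesh(5, 10, n_around = 128)
  expect_equal(cylinder_soil_volume(cyl), pi * 25 * 10, tolerance = 0.01)
  cube <- box_mesh(c(1, 1, 1))   # centred on the axis
  expect_equal(cylinder_soil_volume(cube), pi * 0.5, tolerance = 1e-9)
  cr <- generate_crown(crown_spec(n_roots = 6, seed = 23), oracle_h = 0.5)
  expect_gte(cylinder_soil_volume(cr$crown_mesh),
             crown_volume_split(cr$crown_mesh))
})

test_that("compactness, density and surface-to-volume follow their formulas", {
  expect_equal(compactness(500, 1000), 50)
  expect_equal(compactness(1e-4, 1000), 1e-5)
  cyl <- cylinder_mesh(5, 10, n_around = 128)
  expect_equal(compactness(signed_volume(cyl), cylinder_soil_volume(cyl)),
               100, tolerance = 1)
  expect_error(compactness(10, 0), "positive")
  expect_error(compactness(1000, 500), "exceeds")

  expect_equal(root_density(1, 1000), 1)
  expect_equal(root_density(2.5, 5000), 0.5)
  expect_error(root_density(1, 0), "positive")

  expect_equal(surface_to_volume_ratio(6, 1), 6)
  expect_equal(surface_to_volume_ratio(24, 8), 3)
  s <- icosphere_mesh(5, 3)
  expect_equal(surface_to_volume_ratio(surface_area(s), signed_volume(s)),
               3 / 5, tolerance = 0.01)
})

test_that("among equal-volume solids the sphere minimises surface-to-volume", {
  s <- icosphere_mesh(5, 3)
  v <- signed_volume(s)
  cube <- box_mesh(rep(v^(1 / 3), 3))
  slab <- box_mesh(c(4 * v^(1 / 3), v^(1 / 3) / 2, v^(1 / 3) / 2))
  sv <- function(m) surface_area(m) / signed_volume(m)
  expect_lt(sv(s), sv(cube))
  expect_lt(sv(cube), sv(slab))
})

test_that("traits are invariant under rotation about z and scale correctly", {
  cr <- generate_crown(crown_spec(n_roots = 6, seed = 24), oracle_h = 0.5)
  m <- cr$crown_mesh
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- transform_mesh(m, Rz)
  expect_equal(crown_diameter(mr), crown_diameter(m), tolerance = 1e-9)
  expect_equal(cylinder_soil_volume(mr), cylinder_soil_volume(m),
               tolerance = 1e-9)
  expect_equal(signed_volume(mr), signed_volume(m), tolerance = 1e-9)
  s <- 1.7
  ms <- scale_mesh(m, s)
  expect_equal(signed_volume(ms), signed_volume(m) * s^3, tolerance = 1e-9)
  expect_equal(crown_diameter(ms), crown_diameter(m) * s, tolerance = 1e-9)
  comp0 <- compactness(signed_volume(m), cylinder_soil_volume(m))
  comps <- compactness(signed_volume(ms), cylinder_soil_volume(ms))
  expect_equal(comps, comp0, tolerance = 1e-9)
  expect_equal(surface_area(ms) / signed_volume(ms),
               (surface_area(m) / signed_volume(m)) / s, tolerance = 1e-9)
})

test_that("compute_all_traits fills every field near its ledger value", {
  spec <- separated_crown_spec(31)
  cr <- generate_crown(spec, oracle_h = 0.2)
  tr <- compute_all_traits(cr$crown_mesh, root_weight = 2.0,
                           config = list(hub_radius = 5))
  expect_equal(tr$crown_volume_cm3, cr$truth$oracle_volume, tolerance = 0.02)
  expect_equal(tr$cylinder_soil_volume_cm3, cr$truth$cylinder_soil_volume,
               tolerance = 0.01)
  expect_equal(tr$compactness_pct, cr$truth$compactness, tolerance = 0.05)
  expect_equal(tr$root_number, 5L)
  expect_equal(tr$mean_root_length_cm, cr$truth$mean_root_length,
               tolerance = 0.03)
  expect_equal(tr$root_density_g_cm3, 2000 / tr$crown_volume_cm3,
               tolerance = 1e-9)
  expect_equal(tr$surface_to_volume_per_cm,
               tr$crown_surface_area_cm2 / tr$crown_volume_cm3,
               tolerance = 1e-9)
  expect_length(tr$missing, 0L)
  row <- traits_as_row(tr, "p1")
  expect_equal(nrow(row), 1L)
  expect_true(all(c("crown_volume_cm3", "compactness_pct", "root_number")
                  %in% names(row)))
})

test_that("compute_all_traits marks density missing without a weight", {
  cr <- generate_crown(crown_spec(n_roots = 5, seed = 32), oracle_h = 0.5)
  tr <- compute_all_traits(cr$crown_mesh)
  expect_true(is.na(tr$root_density_g_cm3))
  expect_true("root_density" %in% tr$missing)
  expect_false(is.na(tr$crown_volume_cm3))
  expect_error(compute_all_traits(triangle_mesh(matrix(0, 1, 3),
                                                matrix(integer(0), 0, 3))),
               "empty")
})
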