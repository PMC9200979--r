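# Digital dissection: segmentation, centerline length, basal angle, maximum
# diameter, crown-level summaries.

test_that("centerline length matches analytic shapes", {
  # straight tapered cone, axis length 30
  fr <- frustum_mesh(4, 1, 30, axis = c(1, 0, 0), n_around = 24, n_axial = 24)
  expect_equal(root_length(as_segment(fr, attachment = c(0, 0, 0))), 30,
               tolerance = 0.02 * 30)
  # quarter torus, centerline radius 20: length pi * R / 2
  th <- seq(0, pi / 2, length.out = 30)
  qt <- tube_mesh(cbind(20 * cos(th), 0, -20 * sin(th)), 2, 24)
  expect_equal(root_length(as_segment(qt, attachment = c(20, 0, 0))),
               pi * 20 / 2, tolerance = 0.05 * pi * 20 / 2)
  # straight cylinder
  cy <- cylinder_mesh(3, 20, n_around = 32, n_axial = 10)
  expect_equal(root_length(as_segment(cy, attachment = c(0, 0, 0))), 20,
               tolerance = 0.02 * 20)
  # a sphere is a degenerate root: too squat for valid sections
  expect_error(root_length(as_segment(icosphere_mesh(0.8, 2))),
               "cross-sections")
})

test_that("basal angles follow the horizontal-datum convention", {
  horiz <- frustum_mesh(3, 1, 25, axis = c(1, 0, 0), n_around = 24,
                        n_axial = 20)
  expect_equal(root_basal_angle(as_segment(horiz, c(0, 0, 0))), 0,
               tolerance = 0.5)
  vert <- frustum_mesh(3, 1, 25, axis = c(0, 0, -1), n_around = 24,
                       n_axial = 20)
  expect_equal(root_basal_angle(as_segment(vert, c(0, 0, 0))), 90,
               tolerance = 0.5)
  inc45 <- frustum_mesh(3, 1, 25, axis = c(sqrt(0.5), 0, -sqrt(0.5)),
                        n_around = 24, n_axial = 20)
  expect_equal(root_basal_angle(as_segment(inc45, c(0, 0, 0))), 45,
               tolerance = 3)
})

test_that("maximum diameter uses the equivalent-circle convention", {
  cy <- cylinder_mesh(3, 20, n_around = 32, n_axial = 10)
  expect_equal(root_max_diameter(as_segment(cy, c(0, 0, 0))), 6,
               tolerance = 0.02 * 6)
  cone <- frustum_mesh(4, 1, 30, axis = c(1, 0, 0), n_around = 32,
                       n_axial = 24)
  expect_equal(root_max_diameter(as_segment(cone, c(0, 0, 0))), 8,
               tolerance = 0.03 * 8)
  jit <- jitter_vertices(cy, 0.05, seed = 7)   # 0.5 mm noise
  expect_equal(root_max_diameter(as_segment(jit, c(0, 0, 0))), 6,
               tolerance = 0.05 * 6)
})

test_that("dissection recovers count, lengths and angles on separated crowns", {
  for (sd in c(1, 2, 3)) {
    spec <- separated_crown_spec(sd)
    cr <- generate_crown(spec, oracle_h = 0.5)
    segs <- segment_roots(cr$crown_mesh, hub_radius = 5)
    expect_length(segs, 5L)
    tab <- summarize_segments(segs)
    ord <- match_segments_to_truth(segs, cr)
    expect_false(anyDuplicated(ord) > 0)
    truth <- do.call(rbind, lapply(cr$truth$roots, as.data.frame))[ord, ]
    expect_lt(max(abs(tab$length_cm - truth$length_outside_hub) /
                    truth$length_outside_hub), 0.02)
    expect_lt(max(abs(tab$basal_angle_deg - truth$basal_angle)), 3)
    expect_false(any(tab$fused))
  }
})

test_that("dissection handles curved roots within the wider tolerance", {
  spec <- separated_crown_spec(4, curvature = 0.012)
  cr <- generate_crown(spec, oracle_h = 0.5)
  segs <- segment_roots(cr$crown_mesh, hub_radius = 5)
  expect_length(segs, 5L)
  tab <- summarize_segments(segs)
  ord <- match_segments_to_truth(segs, cr)
  truth <- do.call(rbind, lapply(cr$truth$roots, as.data.frame))[ord, ]
  expect_lt(max(abs(tab$length_cm - truth$length_outside_hub) /
                  truth$length_outside_hub), 0.05)
})

test_that("a single-root crown yields one segment", {
  spec <- crown_spec(n_roots = 1, azimuth = 40, inclination = 35, length = 28,
                     basal_radius = 3, tip_radius = 1, curvature = 0, seed = 5)
  cr <- generate_crown(spec, oracle_h = 0.5)
  segs <- segment_roots(cr$crown_mesh, hub_radius = 5)
  expect_length(segs, 1L)
})

test_that("roots fused outside the hub come back as one flagged segment", {
  # two nearly parallel fat roots merged into a single surface by remeshing
  spec <- crown_spec(n_roots = 2, azimuth = c(0, 14), inclination = c(30, 30),
                     length = 28, basal_radius = 3.4, tip_radius = 2.6,
                     curvature = 0, seed = 6)
  cr <- generate_crown(spec, include_stem = FALSE, oracle_h = 0.5)
  fused_surface <- close_holes(cr$crown_mesh, 7)
  segs <- segment_roots(fused_surface, hub_radius = 6)
  expect_length(segs, 1L)
  expect_true(segs[[1]]$fused)
})

test_that("the hub clearance leaves no segment volume unaccounted", {
  cr <- generate_crown(crown_spec(n_roots = 6, seed = 7), oracle_h = 0.3)
  segs <- segment_roots(cr$crown_mesh, hub_radius = 5)
  total <- sum(vapply(segs, `[[`, numeric(1), "volume"))
  expect_lt(total, cr$truth$oracle_volume)
})

test_that("crown root angle averages the k lowest angles", {
  expect_equal(crown_root_angle(c(10, 20, 30, 80), k = 3), 20)
  expect_equal(crown_root_angle(c(30, 30, 30, 30), k = 3), 30)
  expect_warning(a <- crown_root_angle(c(50), k = 3), "using all")
  expect_equal(a, 50)
  expect_error(crown_root_angle(numeric(0)), "no root angles")
  # permutation invariance
  set.seed(3)
  angs <- runif(8, 0, 90)
  expect_equal(crown_root_angle(angs), crown_root_angle(sample(angs)))
})

test_that("mean root length is rotation invariant", {
  spec <- separated_crown_spec(8)
  cr <- generate_crown(spec, oracle_h = 0.5)
  segs <- segment_roots(cr$crown_mesh, hub_radius = 5)
  m0 <- mean(summarize_segments(segs)$length_cm)
  th <- 0.8
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  segs_r <- segment_roots(transform_mesh(cr$crown_mesh, Rz), hub_radius = 5)
  m1 <- mean(summarize_segments(segs_r)$length_cm)
  expect_equal(m1, m0, tolerance = 0.01)
})
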