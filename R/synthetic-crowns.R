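# ---------------------------------------------------------------------------
# Procedural root-crown fixtures with exact ground truth. The generator
# emulates what photogrammetry delivers for an excavated cassava root crown:
# a stem stub, a hub, radiating tapered storage roots, and (optionally) a
# blind-area defect, floating noise and vertex jitter. Ground truth comes
# from the voxel oracle, the package's stand-in for water displacement.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic root crown
#'
#' Fully determines one procedural crown. Per-root parameters are vectors of
#' length `n_roots`: azimuth (deg), inclination below the horizontal (deg,
#' 0 = horizontal, 90 = straight down), centerline length (cm), basal and
#' tip radii (cm) and curvature (1/cm, bending the root further downward
#' along its run). Defaults reflect field-grown storage-root crowns at
#' harvest: 5-10 storage roots, 15-35 cm long, basal diameters 4-8 cm.
#'
#' @param n_roots number of storage roots.
#' @param azimuth,inclination,length,basal_radius,tip_radius,curvature
#'   per-root parameters (recycled to `n_roots`); when `NULL`, drawn from
#'   realistic ranges using `seed`.
#' @param stem_radius,stem_height stem stub cylinder (cm).
#' @param hub_radius radius (cm) of the hub sphere joining the root bases.
#' @param mesh_resolution axial stations per root.
#' @param n_around circumferential resolution of tubes.
#' @param seed integer; fully determines the drawn parameters.
#' @return object of class `crown_spec`.
#' @export
crown_spec <- function(n_roots = 7L, azimuth = NULL, inclination = NULL,
                       length = NULL, basal_radius = NULL, tip_radius = NULL,
                       curvature = NULL, stem_radius = 2, stem_height = 10,
                       hub_radius = 5, mesh_resolution = 14L, n_around = 12L,
                       seed = 1L) {
  n_roots <- as.integer(n_roots)
  if (n_roots < 1L) stop("n_roots must be >= 1")
  drawn <- with_seed(seed, {
    az <- if (is.null(azimuth)) {
      base <- seq(0, 360, length.out = n_roots + 1L)[seq_len(n_roots)]
      jit <- runif(n_roots, -0.25, 0.25) * 360 / n_roots
      (base + jit) %% 360
    } else rep_len(azimuth, n_roots)
    inc <- if (is.null(inclination)) runif(n_roots, 15, 55) else
      rep_len(inclination, n_roots)
    len <- if (is.null(length)) runif(n_roots, 15, 35) else
      rep_len(length, n_roots)
    rb <- if (is.null(basal_radius)) runif(n_roots, 2.5, 4.5) else
      rep_len(basal_radius, n_roots)
    rt <- if (is.null(tip_radius)) pmin(runif(n_roots, 0.5, 1.2), rb * 0.8) else
      rep_len(tip_radius, n_roots)
    cv <- if (is.null(curvature)) runif(n_roots, 0, 0.015) else
      rep_len(curvature, n_roots)
    list(az = az, inc = inc, len = len, rb = rb, rt = rt, cv = cv)
  })
  if (any(drawn$inc < 0 | drawn$inc > 90)) stop("inclination must be in [0, 90]")
  if (any(drawn$len <= 0) || any(drawn$rb <= 0) || any(drawn$rt <= 0))
    stop("root lengths and radii must be positive")
  structure(list(
    n_roots = n_roots, azimuth = drawn$az, inclination = drawn$inc,
    length = drawn$len, basal_radius = drawn$rb, tip_radius = drawn$rt,
    curvature = drawn$cv, stem_radius = stem_radius, stem_height = stem_height,
    hub_radius = hub_radius, mesh_resolution = as.integer(mesh_resolution),
    n_around = as.integer(n_around), seed = as.integer(seed)),
    class = "crown_spec")
}

# curved root centerline: starts at `start` heading (azimuth, inclination),
# curvature steepens the dive linearly with arc length
root_centerline <- function(azimuth, inclination, length, curvature,
                            k = 14L, start = c(0, 0, 0)) {
  s <- seq(0, length, length.out = max(2L, k))
  az <- azimuth * pi / 180
  pts <- matrix(0, length(s), 3L)
  inc <- inclination * pi / 180
  pos <- start
  pts[1L, ] <- pos
  for (i in seq_along(s)[-1L]) {
    ds <- s[i] - s[i - 1L]
    th <- pmin(inc + curvature * s[i - 1L], pi / 2)
    d <- c(cos(az) * cos(th), sin(az) * cos(th), -sin(th))
    pos <- pos + d * ds
    pts[i, ] <- pos
  }
  pts
}

# arc length of a polyline centerline outside the cylindrical hub clearance,
# and the basal direction angle of its first quarter (what digital
# dissection can actually see once the hub is removed)
centerline_outside_hub <- function(cl, hub_radius) {
  r <- sqrt(cl[, 1]^2 + cl[, 2]^2)
  out <- r >= hub_radius
  if (!any(out)) return(list(length = 0, basal_angle = NA_real_))
  i0 <- which(out)[1]
  pts <- cl[max(1L, i0 - 1L):nrow(cl), , drop = FALSE]
  if (i0 > 1L) {
    # interpolate the exact exit point on the hub cylinder
    a <- pts[1L, ]; b <- pts[2L, ]
    ra <- sqrt(sum(a[1:2]^2)); rb <- sqrt(sum(b[1:2]^2))
    t <- if (rb > ra) (hub_radius - ra) / (rb - ra) else 0
    pts[1L, ] <- a + t * (b - a)
  }
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  len <- sum(seglen)
  cum <- cumsum(seglen)
  i25 <- max(1L, which(cum >= 0.25 * len)[1])
  d25 <- pts[i25 + 1L, ] - pts[1L, ]
  ang <- asin(abs(d25[3]) / sqrt(sum(d25^2))) * 180 / pi
  list(length = len, basal_angle = ang)
}

#' Generate a synthetic root crown with ground truth
#'
#' Builds the crown as a union of closed components: a hub sphere at the
#' origin, one tapered (possibly curved) tube per storage root, and a stem
#' cylinder rising above the soil line z = 0. Components overlap at the hub,
#' so the ledger volume is computed by the voxel oracle on the union, never
#' by summing analytic part volumes. Output is bit-deterministic per spec.
#'
#' @param spec a [crown_spec()].
#' @param include_stem include the stem stub (default `TRUE`).
#' @param include_hub include the hub sphere (default `TRUE`).
#' @param oracle_h voxel size (cm) for the ground-truth volume (default 0.1,
#'   i.e. 1 mm).
#' @return list with `mesh` (full crown, canonical frame), `crown_mesh`
#'   (stem removed, i.e. roots + hub only) and `truth` (ground-truth ledger:
#'   oracle volumes, per-root length/angle/diameter, root count, cylinder
#'   soil volume, compactness, support side).
#' @export
generate_crown <- function(spec, include_stem = TRUE, include_hub = TRUE,
                           oracle_h = 0.1) {
  stopifnot(inherits(spec, "crown_spec"))
  hub_center <- c(0, 0, -max(0, spec$hub_radius - 1))
  parts <- list()
  root_truth <- vector("list", spec$n_roots)
  for (i in seq_len(spec$n_roots)) {
    cl <- root_centerline(spec$azimuth[i], spec$inclination[i], spec$length[i],
                          spec$curvature[i], spec$mesh_resolution,
                          start = hub_center)
    t <- seq(0, 1, length.out = nrow(cl))
    radii <- spec$basal_radius[i] + t * (spec$tip_radius[i] - spec$basal_radius[i])
    parts[[length(parts) + 1L]] <- tube_mesh(cl, radii, spec$n_around)
    seglen <- sqrt(rowSums(diff(cl)^2))
    full_len <- sum(seglen)
    vis <- centerline_outside_hub(cl, spec$hub_radius)
    # radius of the visible (outside-hub) part at its basal end
    s_exit <- max(0, full_len - vis$length)
    r_exit <- spec$basal_radius[i] +
      (spec$tip_radius[i] - spec$basal_radius[i]) * s_exit / full_len
    root_truth[[i]] <- list(length = full_len,
                            length_outside_hub = vis$length,
                            basal_angle = vis$basal_angle,
                            inclination = spec$inclination[i],
                            basal_diameter = 2 * spec$basal_radius[i],
                            visible_basal_diameter = 2 * r_exit)
  }
  if (include_hub)
    parts[[length(parts) + 1L]] <-
      icosphere_mesh(spec$hub_radius, 3L, center = hub_center)
  label <- sprintf("synthetic crown seed %d", spec$seed)
  assembly <- merge_meshes(parts, label = label)
  # crown proper: the part below the soil line z = 0
  crown_mesh <- plane_cut(assembly, mesh_plane(c(0, 0, 0), c(0, 0, 1)))$below
  if (is.null(crown_mesh)) stop("degenerate spec: nothing below the soil line")
  crown_mesh$label <- label
  full <- if (include_stem) {
    stem <- cylinder_mesh(spec$stem_radius, spec$stem_height + 2,
                          base = c(0, 0, -2), n_around = spec$n_around,
                          n_axial = 10L)
    merge_meshes(c(parts, list(stem)), label = label)
  } else assembly

  oracle_volume <- voxel_volume(crown_mesh, h = oracle_h)
  v <- crown_mesh$vertices
  r_max <- max(sqrt(v[, 1]^2 + v[, 2]^2))
  zext <- max(v[, 3]) - min(v[, 3])
  cyl <- pi * r_max^2 * zext
  truth <- list(
    oracle_volume = oracle_volume,
    oracle_volume_full = voxel_volume(full, h = oracle_h),
    oracle_area = surface_area(crown_mesh),
    root_count = spec$n_roots,
    roots = root_truth,
    mean_root_length = mean(vapply(root_truth, `[[`, numeric(1),
                                   "length_outside_hub")),
    cylinder_soil_volume = cyl,
    compactness = 100 * oracle_volume / cyl,
    support_normal = c(0, -1, 0),
    oracle_h = oracle_h)
  list(mesh = full, crown_mesh = crown_mesh, truth = truth, spec = spec)
}

#' Inject a photogrammetry blind-area defect
#'
#' Removes every face whose centroid lies within `depth` of the supporting
#' plane on the support side, opening the mesh the way the unphotographable
#' contact region does in real reconstructions.
#'
#' @param mesh watertight `triangle_mesh`.
#' @param support_normal unit 3-vector pointing from the crown towards the
#'   support surface (default -y: the crown lies on its side).
#' @param depth extent (cm) of the blind band measured from the support
#'   plane.
#' @return open `triangle_mesh` (unchanged when `depth` is 0).
#' @export
inject_blind_area_defect <- function(mesh, support_normal = c(0, -1, 0),
                                     depth = 1) {
  stopifnot_mesh(mesh)
  if (depth < 0) stop("depth must be >= 0")
  if (depth == 0) return(mesh)
  n <- support_normal / sqrt(sum(support_normal^2))
  t <- as.vector(mesh$vertices %*% n)
  if (depth >= max(t) - min(t))
    stop("defect depth exceeds the mesh extent along the support normal")
  co <- face_corners(mesh)
  cent_t <- (as.vector(co$a %*% n) + as.vector(co$b %*% n) +
             as.vector(co$c %*% n)) / 3
  keep <- cent_t < max(t) - depth  # support plane is at max t along n
  if (!any(keep)) stop("defect depth removes the whole mesh")
  out <- mesh
  out$faces <- mesh$faces[keep, , drop = FALSE]
  out
}

#' Jitter mesh vertices
#'
#' Adds isotropic Gaussian displacement (reconstruction noise at the
#' millimetre scale). Deterministic per seed.
#'
#' @param mesh a `triangle_mesh`.
#' @param sigma standard deviation (cm) of the displacement.
#' @param seed integer seed.
#' @return jittered `triangle_mesh`.
#' @export
jitter_vertices <- function(mesh, sigma, seed = 1L) {
  stopifnot_mesh(mesh)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(mesh)
  nv <- nrow(mesh$vertices)
  mesh$vertices <- mesh$vertices +
    with_seed(seed, matrix(rnorm(3L * nv, sd = sigma), nv, 3L))
  mesh
}

#' Add floating noise components
#'
#' Scatters small tetrahedra around the crown, emulating background remnants
#' that survive manual clean-up.
#'
#' @param mesh a `triangle_mesh`.
#' @param n number of floaters.
#' @param size floater edge length (cm).
#' @param seed integer seed.
#' @return `triangle_mesh` with floaters appended.
#' @export
add_floating_noise <- function(mesh, n = 20L, size = 0.5, seed = 1L) {
  stopifnot_mesh(mesh)
  if (n == 0L) return(mesh)
  b <- bbox_mesh(mesh)
  floaters <- with_seed(seed, lapply(seq_len(n), function(i) {
    ctr <- runif(3, b[1, ] - 5, b[2, ] + 5)
    v <- rbind(c(0, 0, 0), c(size, 0, 0), c(0, size, 0), c(0, 0, size))
    m <- triangle_mesh(sweep(v, 2L, -ctr),
                       rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
    m
  }))
  merge_meshes(c(list(mesh), floaters), label = mesh$label)
}

#' Simulate the blind-area volume benchmark cohort
#'
#' The standard benchmark for the split-half protocol: crowded crowns
#' (9-14 storage roots at unconstrained azimuths, so roots collide and run
#' close together the way field-grown crowns do), each given a blind-area
#' defect on the support side, then measured two ways — the repaired intact
#' mesh, and the split-half protocol — against the voxel-oracle ground
#' truth.
#'
#' @param n cohort size.
#' @param seed integer; crown i derives its seed from `seed * 1000 + i`.
#' @param depth blind-area defect depth (cm).
#' @param octree_depth remesh resolution parameter.
#' @return data.frame with one row per crown: `oracle_volume_cm3`,
#'   `intact_volume_cm3`, `split_volume_cm3`, `n_roots`, `seed`.
#' @export
simulate_defect_cohort <- function(n = 20L, seed = 1L, depth = 1.5,
                                   octree_depth = 8L) {
  rows <- lapply(seq_len(n), function(i) {
    si <- (seed * 1000L + i) %% .Machine$integer.max
    n_roots <- with_seed(si, sample(9:14, 1))
    azimuth <- with_seed(si * 3L + 1L, runif(n_roots, 0, 360))
    spec <- crown_spec(n_roots = n_roots, azimuth = azimuth, seed = si)
    cr <- generate_crown(spec)
    def <- inject_blind_area_defect(cr$crown_mesh,
                                    cr$truth$support_normal, depth = depth)
    intact <- signed_volume(close_holes(def, octree_depth), check = FALSE)
    split <- crown_volume_split(def, cr$truth$support_normal, octree_depth)
    data.frame(oracle_volume_cm3 = cr$truth$oracle_volume,
               intact_volume_cm3 = intact, split_volume_cm3 = split,
               n_roots = n_roots, seed = si)
  })
  do.call(rbind, rows)
}

#' Simulate a field-trial dataset under an augmented RCBD
#'
#' Generates trial records for the augmented randomized complete block
#' design used in cassava single-row trials: replicated check varieties in
#' every block, unreplicated test genotypes assigned round-robin to blocks.
#' Each observation is `mean + genotype effect + block effect + error` with
#' independent Gaussian components of the stated variances.
#'
#' @param n_test_genotypes unreplicated test entries.
#' @param n_checks check varieties (replicated in every block), >= 2.
#' @param n_blocks blocks, >= 2.
#' @param sigma2_G,sigma2_block,sigma2_e variance components (genotypic,
#'   block, residual).
#' @param trait_mean grand mean of the simulated trait.
#' @param trait trait column name.
#' @param seed integer seed.
#' @return data.frame with columns `genotype_id`, `block_id`, `is_check`,
#'   and the trait, plus attribute `true_effects`.
#' @export
make_trial_dataset <- function(n_test_genotypes = 29L, n_checks = 5L,
                               n_blocks = 9L, sigma2_G = 1, sigma2_block = 1,
                               sigma2_e = 1, trait_mean = 100,
                               trait = "value", seed = 1L) {
  if (n_checks < 2L) stop("need at least 2 checks")
  if (n_blocks < 2L) stop("need at least 2 blocks")
  if (any(c(sigma2_G, sigma2_block, sigma2_e) < 0))
    stop("variance components must be non-negative")
  with_seed(seed, {
    g_test <- rnorm(n_test_genotypes, sd = sqrt(sigma2_G))
    g_check <- rnorm(n_checks, sd = sqrt(sigma2_G))
    b_eff <- rnorm(n_blocks, sd = sqrt(sigma2_block))
    checks <- expand.grid(check = seq_len(n_checks), block = seq_len(n_blocks))
    test_block <- rep(seq_len(n_blocks), length.out = n_test_genotypes)
    rec_check <- data.frame(
      genotype_id = sprintf("check_%02d", checks$check),
      block_id = sprintf("block_%02d", checks$block),
      is_check = TRUE,
      value = trait_mean + g_check[checks$check] + b_eff[checks$block] +
        rnorm(nrow(checks), sd = sqrt(sigma2_e)))
    rec_test <- data.frame(
      genotype_id = sprintf("test_%03d", seq_len(n_test_genotypes)),
      block_id = sprintf("block_%02d", test_block),
      is_check = FALSE,
      value = trait_mean + g_test + b_eff[test_block] +
        rnorm(n_test_genotypes, sd = sqrt(sigma2_e)))
    out <- rbind(rec_check, rec_test)
    names(out)[names(out) == "value"] <- trait
    attr(out, "true_effects") <- list(g_test = g_test, g_check = g_check,
                                      block = b_eff)
    out
  })
}
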