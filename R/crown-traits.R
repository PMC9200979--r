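# ---------------------------------------------------------------------------
# Whole-crown traits: split-half volume, surface area, diameter, cylinder
# soil volume, compactness, density, surface-to-volume ratio, aggregation.
# All operate on a prepped crown (stem removed, canonical frame, cm units).
# ---------------------------------------------------------------------------

#' Crown volume by the split-half protocol
#'
#' Separates the crown into two halves with the vertical plane that contains
#' the stem axis and whose normal is the support-side direction, re-closes
#' each half independently, and returns the sum of the two half volumes.
#' Splitting before closing reduces the volume bias contributed by the
#' blind-area defect and by narrow inter-root spaces that a whole-crown
#' remesh amalgamates: each half is rebuilt on its own, finer grid and the
#' cut exposes the crowded hub region exactly.
#'
#' For a watertight input the halves are produced by an exact [plane_cut()]
#' (volumes conserve to round-off); an open input is partitioned and each
#' half is closed volumetrically with [close_holes()].
#'
#' @param mesh crown `triangle_mesh` (stem removed, canonical frame).
#' @param support_normal horizontal support-side direction; the split plane
#'   normal (default -y, the side the crown rested on).
#' @param octree_depth remesh resolution for re-closing open halves.
#' @return volume in cm^3.
#' @export
crown_volume_split <- function(mesh, support_normal = c(0, -1, 0),
                               octree_depth = 8L) {
  stopifnot_mesh(mesh)
  n <- c(support_normal[1], support_normal[2], 0)
  if (sqrt(sum(n^2)) < 1e-12) n <- c(0, 1, 0)
  n <- n / sqrt(sum(n^2))
  pl <- mesh_plane(c(0, 0, 0), n)
  if (is_watertight(mesh)) {
    halves <- plane_cut(mesh, pl)
    vols <- vapply(Filter(Negate(is.null), halves), signed_volume,
                   numeric(1), check = FALSE)
    return(sum(vols))
  }
  # open input: cap the cut cross-section exactly (so the remesher sees a
  # closed boundary everywhere except the blind-area hole), then re-close
  # each half volumetrically; the remesh resolves overlapping components
  # into their union, consistent with the intact-mesh estimate
  parts <- partition_by_plane(mesh, pl, cap = TRUE)
  halves <- Filter(Negate(is.null), parts)
  if (length(halves) == 0L) stop("split produced no halves")
  # when the split plane is axis-aligned, snap the remesh lattice onto it
  # so the flat cut is represented exactly
  ax <- which(abs(abs(n) - 1) < 1e-9)
  snap <- if (length(ax) == 1L) list(axis = ax, value = 0) else NULL
  vols <- vapply(halves, function(hm) {
    closed <- tryCatch(close_holes(hm, octree_depth, snap = snap),
                       error = function(e) stop("non-closeable half: ",
                                                conditionMessage(e)))
    signed_volume(closed, check = FALSE)
  }, numeric(1))
  sum(vols)
}

#' Crown diameter (maximum horizontal caliper)
#'
#' Maximum pairwise distance among vertices projected onto the soil plane
#' z = 0, so a deep vertical root does not inflate the diameter.
#'
#' @param mesh crown `triangle_mesh` in the canonical frame.
#' @return diameter in cm.
#' @export
crown_diameter <- function(mesh) {
  stopifnot_mesh(mesh)
  p <- mesh$vertices[, 1:2, drop = FALSE] * mesh$unit_scale
  hull <- grDevices::chull(p[, 1], p[, 2])
  hp <- p[hull, , drop = FALSE]
  if (nrow(hp) == 1L) return(0)
  d2 <- as.matrix(stats::dist(hp))
  max(d2)
}

#' Cylinder soil volume
#'
#' Volume of the minimal enclosing vertical cylinder: axis = stem axis (z),
#' radius = maximum radial vertex distance from the axis, height = vertical
#' extent of the crown. Represents the soil space the crown occupies.
#'
#' @param mesh crown `triangle_mesh` (stem removed, canonical frame).
#' @return volume in cm^3.
#' @export
cylinder_soil_volume <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices * mesh$unit_scale
  r <- max(sqrt(v[, 1]^2 + v[, 2]^2))
  h <- max(v[, 3]) - min(v[, 3])
  pi * r^2 * h
}

#' Crown compactness
#'
#' Percentage of the cylinder soil volume filled by the crown:
#' `100 * crown_volume / cylinder_volume`. Measures how effectively the
#' crown uses its soil space.
#'
#' @param crown_volume crown volume (cm^3), > 0.
#' @param cylinder_volume enclosing-cylinder volume (cm^3), > 0 and >=
#'   `crown_volume`.
#' @return compactness in percent, in (0, 100].
#' @export
compactness <- function(crown_volume, cylinder_volume) {
  if (cylinder_volume <= 0) stop("cylinder_volume must be positive")
  if (crown_volume <= 0) stop("crown_volume must be positive")
  if (crown_volume > cylinder_volume * (1 + 1e-9))
    stop("inconsistent inputs: crown volume exceeds its enclosing cylinder")
  100 * crown_volume / cylinder_volume
}

#' Root density
#'
#' Fresh root weight per crown volume, `1000 * weight_kg / volume_cm3`,
#' reported in g/cm^3.
#'
#' @param root_weight fresh weight in kg, > 0.
#' @param crown_volume crown volume in cm^3, > 0.
#' @return density in g/cm^3.
#' @export
root_density <- function(root_weight, crown_volume) {
  if (root_weight <= 0) stop("root_weight must be positive")
  if (crown_volume <= 0) stop("crown_volume must be positive")
  1000 * root_weight / crown_volume
}

#' Surface-to-volume ratio
#'
#' Crown area over crown volume (1/cm). Lower values indicate shorter or
#' thicker roots; higher values longer or thinner roots.
#'
#' @param area surface area in cm^2, > 0.
#' @param volume volume in cm^3, > 0.
#' @return ratio in 1/cm.
#' @export
surface_to_volume_ratio <- function(area, volume) {
  if (area <= 0) stop("area must be positive")
  if (volume <= 0) stop("volume must be positive")
  area / volume
}

#' Compute the full crown trait set
#'
#' Aggregates every whole-crown trait plus the dissection summaries for one
#' prepped crown (stem removed, canonical frame, cm units). Components that
#' fail (e.g. dissection of a degenerate mesh) leave their fields `NA` and
#' are listed in `$missing`.
#'
#' @param mesh crown `triangle_mesh`.
#' @param root_weight fresh root weight in kg, or `NULL` if not recorded.
#' @param config list of settings: `support_normal`, `octree_depth`,
#'   `hub_radius`, `min_root_volume`, `k_lowest_angles`.
#' @return object of class `crown_traits`: a list of the ten traits, the
#'   per-root table, and a provenance block with the settings used.
#' @export
compute_all_traits <- function(mesh, root_weight = NULL, config = list()) {
  stopifnot_mesh(mesh)
  cfg <- utils::modifyList(list(support_normal = c(0, -1, 0),
                                octree_depth = 8L, hub_radius = 5,
                                min_root_volume = 5, k_lowest_angles = 3L),
                           config)
  missing <- character(0)
  watertight_input <- is_watertight(mesh)
  # a multi-component assembly (overlapping closed parts) must be resolved
  # into its union before measurement; a single closed surface is used as-is
  single <- watertight_input &&
    length(connected_components(mesh)) == 1L
  closed <- if (single) mesh else close_holes(mesh, cfg$octree_depth)

  vol <- crown_volume_split(closed, cfg$support_normal, cfg$octree_depth)
  area <- surface_area(closed)
  diam <- crown_diameter(closed)
  cyl <- cylinder_soil_volume(closed)
  comp <- compactness(min(vol, cyl), cyl)
  s2v <- surface_to_volume_ratio(area, vol)
  dens <- if (is.null(root_weight)) {
    missing <- c(missing, "root_density")
    NA_real_
  } else root_density(root_weight, vol)

  # dissect the least-processed geometry: the remeshed union can fuse
  # adjacent roots that are distinct in the input surface
  segs <- tryCatch(segment_roots(mesh, hub_radius = cfg$hub_radius,
                                 min_volume = cfg$min_root_volume),
                   error = function(e) NULL)
  if (is.null(segs)) {
    missing <- c(missing, "root_number", "crown_root_angle", "mean_root_length")
    n_roots <- NA_integer_; cra <- NA_real_; mrl <- NA_real_
    per_root <- NULL
  } else {
    per_root <- summarize_segments(segs)
    n_roots <- nrow(per_root)
    angs <- per_root$basal_angle_deg[!is.na(per_root$basal_angle_deg)]
    cra <- if (length(angs)) crown_root_angle(angs, k = cfg$k_lowest_angles)
           else NA_real_
    mrl <- mean(per_root$length_cm, na.rm = TRUE)
  }

  structure(list(
    crown_volume_cm3 = vol,
    crown_surface_area_cm2 = area,
    crown_diameter_cm = diam,
    cylinder_soil_volume_cm3 = cyl,
    compactness_pct = comp,
    root_density_g_cm3 = dens,
    surface_to_volume_per_cm = s2v,
    root_number = n_roots,
    crown_root_angle_deg = cra,
    mean_root_length_cm = mrl,
    root_weight_kg = if (is.null(root_weight)) NA_real_ else root_weight,
    per_root = per_root,
    missing = missing,
    provenance = c(cfg, list(watertight_input = watertight_input,
                             n_faces = nrow(mesh$faces)))),
    class = "crown_traits")
}

#' @export
print.crown_traits <- function(x, ...) {
  cat("Crown traits:\n")
  flds <- c("crown_volume_cm3", "crown_surface_area_cm2", "crown_diameter_cm",
            "cylinder_soil_volume_cm3", "compactness_pct",
            "root_density_g_cm3", "surface_to_volume_per_cm", "root_number",
            "crown_root_angle_deg", "mean_root_length_cm", "root_weight_kg")
  for (f in flds) cat(sprintf("  %-26s %s\n", f, format(x[[f]], digits = 6)))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' One-row data frame of the trait set
#' @param x a `crown_traits` object.
#' @param plant_id identifier for the row.
#' @return data.frame with one row.
#' @export
traits_as_row <- function(x, plant_id = "plant") {
  stopifnot(inherits(x, "crown_traits"))
  data.frame(plant_id = plant_id,
             crown_volume_cm3 = x$crown_volume_cm3,
             crown_surface_area_cm2 = x$crown_surface_area_cm2,
             crown_diameter_cm = x$crown_diameter_cm,
             cylinder_soil_volume_cm3 = x$cylinder_soil_volume_cm3,
             compactness_pct = x$compactness_pct,
             root_density_g_cm3 = x$root_density_g_cm3,
             surface_to_volume_per_cm = x$surface_to_volume_per_cm,
             root_number = x$root_number,
             crown_root_angle_deg = x$crown_root_angle_deg,
             mean_root_length_cm = x$mean_root_length_cm,
             root_weight_kg = x$root_weight_kg,
             stringsAsFactors = FALSE)
}
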