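# ---------------------------------------------------------------------------
# From raw photogrammetry export to analysis-ready crown: noise clearing,
# watertight repair, scale calibration, canonical orientation, stem removal.
# ---------------------------------------------------------------------------

#' Remove floating noise components
#'
#' Keeps every edge-connected component whose face count is at least
#' `min_fraction` of the largest component's face count. Small floating
#' fragments left over from background removal are dropped; the largest
#' component is never removed.
#'
#' @param mesh a `triangle_mesh`.
#' @param min_fraction fraction in (0, 1) of the largest component's face
#'   count below which a component is discarded.
#' @return cleaned `triangle_mesh`.
#' @export
remove_noise_components <- function(mesh, min_fraction = 0.01) {
  stopifnot_mesh(mesh)
  if (min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must be in (0, 1)")
  comps <- connected_components(mesh)
  nf <- vapply(comps, function(m) nrow(m$faces), integer(1))
  keep <- nf >= min_fraction * max(nf)
  removed <- sum(!keep)
  if (removed > 0L)
    message(sprintf("remove_noise_components: dropped %d small component(s)", removed))
  if (all(keep)) return(mesh)
  merge_meshes(comps[keep], label = mesh$label)
}

#' Close holes by volumetric remeshing
#'
#' Re-creates a watertight surface from a (possibly open) mesh, emulating a
#' volumetric "remesh" repair: the interior is rasterised on a voxel grid at
#' resolution `bounding-box diagonal / 2^octree_depth` using signed
#' ray-crossing occupancy voted over the three axis directions, the boundary
#' isosurface is extracted, and the staircase is relaxed by Taubin
#' smoothing. For an already-closed input the volume changes by well under
#' 2 percent at the default depth.
#'
#' @param mesh a `triangle_mesh`, open or closed.
#' @param octree_depth grid refinement; resolution is
#'   `bbox diagonal / 2^octree_depth` (default 8).
#' @param smooth_iterations Taubin passes applied to the extracted surface.
#' @param snap optional `list(axis =, value =)`: force one lattice plane
#'   onto the given coordinate plane so a flat cut lying there is captured
#'   exactly (used by the split-half protocol).
#' @return a watertight `triangle_mesh`.
#' @export
close_holes <- function(mesh, octree_depth = 8L, smooth_iterations = 5L,
                        snap = NULL) {
  stopifnot_mesh(mesh)
  h <- bbox_diagonal(mesh) / 2^octree_depth
  # guard the grid size (very anisotropic bounding boxes)
  g <- voxel_grid_spec(mesh, h, snap = snap)
  while (prod(as.double(g$dims)) > 4e7) {
    h <- h * 1.26
    g <- voxel_grid_spec(mesh, h, snap = snap)
  }
  og <- occupancy_grid(mesh, h, snap = snap)
  if (!any(og$occ)) stop("no enclosed volume")
  og$occ <- fill_hinges(morph_close(og$occ))
  out <- occupancy_isosurface(og$occ, og$origin, og$h,
                              unit_scale = mesh$unit_scale, label = mesh$label)
  if (smooth_iterations > 0L) out <- taubin_smooth(out, smooth_iterations)
  out
}

#' Calibrate scene scale from a reference object
#'
#' Computes the minimal oriented bounding box (OBB) of the reference mesh
#' (the cuboid box photographed next to the crown, which lies at arbitrary
#' pose), selects one of its three sorted extents, and rescales the whole
#' scene so that extent equals its known physical size. After calibration
#' coordinates are in cm and `unit_scale` is 1.
#'
#' @param scene `triangle_mesh` to rescale (typically the crown).
#' @param reference `triangle_mesh` of the cuboid reference object.
#' @param known_dim_cm physical size (cm) of the selected reference extent.
#' @param dim_selector which sorted OBB extent the known size refers to.
#' @return list with `mesh` (rescaled scene) and `calibration` (scale factor,
#'   measured reference extents in cm, known extent).
#' @export
calibrate_scale <- function(scene, reference, known_dim_cm = 34,
                            dim_selector = c("longest", "shortest", "middle")) {
  stopifnot_mesh(scene)
  if (!inherits(reference, "triangle_mesh") || is_empty_mesh(reference))
    stop("calibration error: reference mesh is empty")
  dim_selector <- match.arg(dim_selector)
  if (known_dim_cm <= 0) stop("known_dim_cm must be positive")
  ext <- sort(min_obb_extents(reference))
  if (min(ext) < 1e-12) stop("calibration error: degenerate reference mesh")
  sel <- switch(dim_selector, shortest = ext[1], middle = ext[2], longest = ext[3])
  sf <- known_dim_cm / sel
  scene <- scale_mesh(scene, sf)
  scene$unit_scale <- 1.0
  list(mesh = scene,
       calibration = list(scale_factor = sf,
                          reference_dims_measured = ext * sf,
                          known_dim_cm = known_dim_cm,
                          dim_selector = dim_selector))
}

# Minimal oriented bounding box extents. Candidate box axes are taken from
# the mesh's own (area-weighted, deduplicated) face normals plus the vertex
# principal axes; for each candidate the 2D minimum-area rectangle of the
# projection is found by rotating calipers. Exact for cuboid meshes.
min_obb_extents <- function(mesh) {
  v <- mesh$vertices
  co <- face_corners(mesh)
  nrm <- cross3(co$b - co$a, co$c - co$a)
  a2 <- sqrt(rowSums(nrm * nrm))
  ok <- a2 > 1e-14
  nrm <- nrm[ok, , drop = FALSE] / a2[ok]
  w <- a2[ok]
  # deduplicate directions (sign-insensitive), keep the heaviest
  flip <- nrm[, 3] < 0 | (nrm[, 3] == 0 & (nrm[, 2] < 0 | (nrm[, 2] == 0 & nrm[, 1] < 0)))
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  key <- paste(round(nrm[, 1], 4), round(nrm[, 2], 4), round(nrm[, 3], 4))
  wsum <- tapply(w, key, sum)
  reps <- nrm[match(names(wsum), key), , drop = FALSE]
  ord <- order(-wsum)
  cand <- reps[ord[seq_len(min(40L, nrow(reps)))], , drop = FALSE]
  pc <- tryCatch(prcomp(v, center = TRUE)$rotation, error = function(e) NULL)
  if (!is.null(pc)) cand <- rbind(cand, t(pc))
  best <- Inf; best_ext <- NULL
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  for (i in seq_len(nrow(cand))) {
    n <- cand[i, ]; n <- n / sqrt(sum(n^2))
    t3 <- as.vector(vc %*% n)
    basis <- plane_basis(n)
    p2 <- vc %*% basis
    r <- min_rect_2d(p2)
    vol <- (max(t3) - min(t3)) * r$area
    if (vol < best) {
      best <- vol
      best_ext <- c(max(t3) - min(t3), r$extents)
    }
  }
  best_ext
}

# minimum-area enclosing rectangle of 2D points (rotating calipers on the
# convex hull); returns area and the two side lengths
min_rect_2d <- function(p2) {
  hull <- grDevices::chull(p2[, 1], p2[, 2])
  hp <- p2[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 1L) return(list(area = 0, extents = c(0, 0)))
  if (nh == 2L) {
    d <- sqrt(sum((hp[2, ] - hp[1, ])^2))
    return(list(area = 0, extents = c(d, 0)))
  }
  best <- Inf; best_ext <- c(0, 0)
  for (e in seq_len(nh)) {
    a <- hp[e, ]; b <- hp[if (e == nh) 1L else e + 1L, ]
    d <- b - a
    len <- sqrt(sum(d^2))
    if (len < 1e-14) next
    d <- d / len
    nrm <- c(-d[2], d[1])
    t1 <- hp %*% d; t2 <- hp %*% nrm
    e1 <- max(t1) - min(t1); e2 <- max(t2) - min(t2)
    if (e1 * e2 < best) { best <- e1 * e2; best_ext <- c(e1, e2) }
  }
  list(area = best, extents = best_ext)
}

#' Orient a crown into the canonical frame
#'
#' Finds the stem stub (a narrow protrusion) and rigidly transforms the mesh
#' so the stem axis points along +z and the stem-crown junction sits at
#' z = 0. The stub is located by scoring candidate directions (principal
#' axes and the direction opposing the mean vertex offset) for a long, thin
#' extremal vertex cluster, then refining the axis as the cluster's first
#' principal component. Azimuth about z is left arbitrary.
#'
#' @param mesh crown `triangle_mesh` with the stem still attached.
#' @param stem_axis optional unit 3-vector overriding detection (direction
#'   from crown towards the stem tip).
#' @return oriented `triangle_mesh` with attributes `rotation` and
#'   `junction_z` describing the applied transform.
#' @export
orient_crown <- function(mesh, stem_axis = NULL) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  if (is.null(stem_axis)) {
    axis <- detect_stem_axis(vc)
  } else {
    axis <- stem_axis / sqrt(sum(stem_axis^2))
  }
  R <- rotation_to_z(axis)
  out <- mesh
  out$vertices <- vc %*% t(R)
  jz <- find_stem_junction(out)
  out$vertices[, 3] <- out$vertices[, 3] - jz
  attr(out, "rotation") <- R
  attr(out, "junction_z") <- jz
  out
}

# Stem-axis search on centred vertices. Every protrusion (stem or root tip)
# shows up as a thin extremal slab, so each candidate direction (principal
# axes and the direction opposing the mean vertex offset, which points away
# from the root mass) is refined to the nearest protrusion axis; the stem is
# then the protrusion about which the rest of the crown is rotationally
# balanced — roots spread around the stem, not around one another.
detect_stem_axis <- function(vc, slab_frac = 0.15) {
  off <- colMeans(vc / pmax(sqrt(rowSums(vc^2)), 1e-12))
  if (sqrt(sum(off^2)) > 1e-8) {
    d <- off / sqrt(sum(off^2))
    ax <- tryCatch(pursue_stem_tip(vc, d), error = function(e) NULL)
    if (!is.null(ax)) return(ax)
  }
  pcs <- t(prcomp(vc)$rotation)
  cand <- rbind(pcs, -pcs)
  if (sqrt(sum(off^2)) > 1e-8) {
    off <- off / sqrt(sum(off^2))
    cand <- rbind(cand, -off, off)
  }
  refine <- function(d) {
    fr <- slab_frac
    for (it in 1:6) {
      t <- as.vector(vc %*% d)
      rng <- max(t) - min(t)
      sel <- t > max(t) - fr * rng
      if (sum(sel) < 8L) return(NULL)
      stub <- vc[sel, , drop = FALSE]
      ax <- prcomp(stub)$rotation[, 1]
      if (sum(ax * d) < 0) ax <- -ax
      d <- ax
      if (it >= 3) fr <- max(0.10, fr * 0.9)
    }
    t <- as.vector(vc %*% d)
    rng <- max(t) - min(t)
    sel <- t > max(t) - fr * rng
    stub <- vc[sel, , drop = FALSE]
    lat <- sweep(stub, 2L, colMeans(stub))
    lat <- lat - outer(as.vector(lat %*% d), d)
    thin <- rng / max(sqrt(mean(rowSums(lat^2))), 1e-9)
    # how far the protrusion sits from the crown's lateral centroid: roots
    # spread around the stem, so the stem stub is laterally central
    stub_ctr <- colMeans(stub)
    stub_lat <- stub_ctr - sum(stub_ctr * d) * d
    all_lat <- vc - outer(as.vector(vc %*% d), d)
    balance <- sqrt(sum(stub_lat^2)) /
      max(sqrt(mean(rowSums(all_lat^2))), 1e-9)
    list(d = d, thin = thin, balance = balance)
  }
  ref <- Filter(Negate(is.null), lapply(seq_len(nrow(cand)),
                                        function(i) refine(cand[i, ])))
  thin <- vapply(ref, `[[`, numeric(1), "thin")
  ok <- thin >= 5
  if (!any(ok))
    stop("orientation failure: no identifiable stem stub; supply stem_axis")
  ref <- ref[ok]
  # storage roots angle downward, so the mean vertex offset points to the
  # stem side: keep candidates in that hemisphere when possible
  if (sqrt(sum(off^2)) > 1e-8) {
    along <- vapply(ref, function(r) sum(r$d * off), numeric(1))
    if (any(along > 0.1)) ref <- ref[along > 0.1]
  }
  bal <- vapply(ref, `[[`, numeric(1), "balance")
  ref[[which.min(bal)]]$d
}

# Tip pursuit: starting from a stem-side direction guess, repeatedly take
# the topmost laterally-central vertex as the stem tip and re-aim at it;
# then fit the stem axis by PCA of the column of points above the widest
# geometry (the hub). Returns NULL-free axis or errors for the caller's
# fallback.
pursue_stem_tip <- function(vc, d, iters = 8L) {
  n <- nrow(vc)
  for (it in seq_len(iters)) {
    t <- as.vector(vc %*% d)
    lat <- vc - outer(t, d)
    latr <- sqrt(rowSums(lat^2))
    central <- latr < 0.25 * max(latr)
    if (sum(central) < 12L) stop("no central column")
    tip_i <- which(central)[which.max(t[central])]
    p_tip <- vc[tip_i, ]
    base <- colMeans(vc[central, , drop = FALSE])
    dn <- p_tip - base
    nn <- sqrt(sum(dn^2))
    if (nn < 1e-9) break
    dn <- dn / nn
    if (sum(abs(dn - d)) < 1e-12) { d <- dn; break }
    d <- dn
  }
  # walk the radius profile down from the tip; the stub ends where the
  # radius jumps (hub or first root shoulder); iterate with the refined axis
  for (fit in 1:3) {
    # centre the probe line on the stem axis, not on a tip-ring vertex
    s0 <- as.vector(sweep(vc, 2L, p_tip) %*% d)
    band <- s0 > -0.05 * (max(s0) - min(s0))
    p_ctr <- colMeans(vc[band, , drop = FALSE])
    p_ctr <- p_ctr + (max(s0[band]) - sum((p_ctr - p_tip) * d)) * d
    rel <- sweep(vc, 2L, p_ctr)
    s <- as.vector(rel %*% d)
    rho <- sqrt(rowSums((rel - outer(s, d))^2))
    rng <- max(s) - min(s)
    bw <- rng / 80
    kbin <- pmax(0L, as.integer(floor(-s / bw)))
    K <- as.integer(floor(0.5 * rng / bw))
    rmax <- vapply(0:K, function(i) {
      x <- rho[kbin == i & s <= bw]
      if (length(x)) max(x) else NA_real_
    }, numeric(1))
    tipbins <- rmax[1:6]
    if (all(is.na(tipbins))) stop("empty tip profile")
    ref <- stats::median(tipbins, na.rm = TRUE)
    jct <- NA_integer_
    for (i in 4:length(rmax)) {
      if (is.na(rmax[i])) next
      if (rmax[i] > 1.5 * ref + 0.01 * rng) { jct <- i; break }
    }
    if (is.na(jct) || jct < 5L) stop("no stem junction on the tip profile")
    stub <- s > -(jct - 1) * bw & s <= bw & rho < 1.5 * ref
    if (sum(stub) < 10L) stop("stem stub too sparse")
    stub_ext <- max(s[stub]) - min(s[stub])
    stub_rms <- sqrt(mean(rho[stub]^2))
    if (stub_ext < 4 * max(stub_rms, 1e-9))
      stop("no elongated stem stub on the tip profile")
    ax <- prcomp(vc[stub, , drop = FALSE])$rotation[, 1]
    if (sum(ax * d) < 0) ax <- -ax
    d <- ax
    sp <- vc[stub, , drop = FALSE]
    p_tip <- sp[which.max(as.vector(sp %*% d)), ]
  }
  d
}

# minimal rotation taking `axis` onto +z (Rodrigues)
rotation_to_z <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  vx <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
          a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(vx^2)); cth <- sum(a * z)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # flip about x
  }
  K <- matrix(c(0, -vx[3], vx[2], vx[3], 0, -vx[1], -vx[2], vx[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# stem-crown junction height: scanning down from the stem tip, the junction
# is where the horizontal spread jumps well above the stem radius
find_stem_junction <- function(mesh, n_bins = 60L) {
  v <- mesh$vertices
  z <- v[, 3]
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  brk <- seq(min(z), max(z), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(z, brk, all.inside = TRUE), 1L), n_bins)
  rmax <- vapply(seq_len(n_bins), function(b) {
    x <- r[bin == b]; if (length(x)) max(x) else NA_real_
  }, numeric(1))
  top <- which(!is.na(rmax))
  top <- top[top > n_bins * 0.7]
  stem_r <- if (length(top)) stats::median(rmax[top]) else min(rmax, na.rm = TRUE)
  wide <- which(!is.na(rmax) & rmax > 2.5 * stem_r)
  if (length(wide) == 0L) return(min(z))
  brk[max(wide) + 1L]
}

#' Remove the stem section
#'
#' Cuts the crown with the horizontal plane z = `cut_height_cm` and returns
#' the closed part below it (the crown proper). If the plane lies above the
#' whole mesh the input is returned unchanged with a warning.
#'
#' @param mesh watertight crown `triangle_mesh` in the canonical frame.
#' @param cut_height_cm height of the cut above the soil line (default 0).
#' @return crown `triangle_mesh` without the stem.
#' @export
remove_stem <- function(mesh, cut_height_cm = 0) {
  stopifnot_mesh(mesh)
  zmax <- max(mesh$vertices[, 3])
  if (cut_height_cm >= zmax) {
    warning("stem cut plane lies above the mesh; returning it unchanged")
    return(mesh)
  }
  res <- plane_cut(mesh, mesh_plane(c(0, 0, cut_height_cm), c(0, 0, 1)))
  if (is.null(res$below)) {
    warning("nothing below the stem cut plane; returning input unchanged")
    return(mesh)
  }
  res$below
}
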