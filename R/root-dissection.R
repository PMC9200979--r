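# ---------------------------------------------------------------------------
# Digital dissection: hub clearance, per-root centerlines, length, basal
# angle, maximum diameter, crown-level root number and lowest-angle summary.
# ---------------------------------------------------------------------------

#' Cross-section loops of a mesh with a plane
#'
#' Intersects the mesh with a plane and chains the resulting segments into
#' closed polygons. Returns, per loop, the 3D polygon, its (absolute) area
#' and area centroid measured in the cutting plane.
#'
#' @param mesh a `triangle_mesh`.
#' @param plane a `mesh_plane`.
#' @return list of loops, each `list(points, area, centroid)`; empty list if
#'   the plane misses the mesh.
#' @export
cross_section_loops <- function(mesh, plane) {
  v <- mesh$vertices
  n <- plane$normal
  d <- as.vector(v %*% n) - sum(plane$point * n)
  eps <- 1e-9 * max(1, max(abs(v)))
  d[abs(d) < eps] <- eps
  f <- mesh$faces
  s <- matrix(d[f] > 0, ncol = 3L)
  mixed <- which(rowSums(s) %in% c(1L, 2L))
  if (length(mixed) == 0L) return(list())
  cross_env <- new.env(parent = emptyenv())
  pts <- list(); np <- 0L
  get_cross <- function(i, j) {
    key <- paste0(min(i, j), "_", max(i, j))
    id <- cross_env[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    np <<- np + 1L
    pts[[np]] <<- v[i, ] + t * (v[j, ] - v[i, ])
    cross_env[[key]] <- np
    np
  }
  edges <- matrix(0L, length(mixed), 2L)  # directed: exit -> entry (pos side)
  for (r in seq_along(mixed)) {
    idx <- f[mixed[r], ]
    ex <- NA_integer_; en <- NA_integer_
    for (e in 1:3) {
      i <- idx[e]; j <- idx[if (e == 3L) 1L else e + 1L]
      if (d[i] > 0 && d[j] < 0) ex <- get_cross(i, j)
      if (d[i] < 0 && d[j] > 0) en <- get_cross(i, j)
    }
    edges[r, ] <- c(ex, en)
  }
  edges <- edges[stats::complete.cases(edges), , drop = FALSE]
  if (nrow(edges) == 0L) return(list())
  P <- do.call(rbind, pts)
  nxt <- edges[, 2]; names(nxt) <- edges[, 1]
  visited <- logical(np)
  basis <- plane_basis(n)
  loops <- list()
  for (st in edges[, 1]) {
    if (visited[st]) next
    loop <- st; cur <- st; ok <- TRUE
    repeat {
      visited[cur] <- TRUE
      nx <- nxt[as.character(cur)]
      if (is.na(nx)) { ok <- FALSE; break }
      if (nx == st) break
      if (visited[nx]) { ok <- FALSE; break }
      loop <- c(loop, nx); cur <- nx
    }
    if (!ok || length(loop) < 3L) next
    p3 <- P[loop, , drop = FALSE]
    p2 <- sweep(p3, 2L, plane$point) %*% basis
    x <- p2[, 1]; y <- p2[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    a2 <- sum(x * yn - xn * y)
    area <- abs(a2) / 2
    if (area < 1e-12) next
    cx <- sum((x + xn) * (x * yn - xn * y)) / (3 * a2)
    cy <- sum((y + yn) * (x * yn - xn * y)) / (3 * a2)
    centroid <- plane$point + basis %*% c(cx, cy)
    loops[[length(loops) + 1L]] <-
      list(points = p3, area = area * mesh$unit_scale^2,
           centroid = as.vector(centroid))
  }
  loops
}

#' Dissect a crown into individual storage roots
#'
#' Removes the hub — every face whose centroid lies within `hub_radius` of
#' the stem axis — and turns each remaining edge-connected component of
#' sufficient volume into one root segment. Components are closed (boundary
#' loops capped) before measurement. Two roots that stay geometrically
#' merged outside the hub come back as a single segment flagged `fused`.
#'
#' @param mesh prepped crown `triangle_mesh` in the canonical frame.
#' @param hub_radius clearance radius (cm) around the stem axis.
#' @param min_volume minimum closed-segment volume (cm^3) for a component to
#'   count as a storage root (suppresses fibrous stubs).
#' @return list of `root_segment` objects.
#' @export
segment_roots <- function(mesh, hub_radius = 5, min_volume = 5) {
  stopifnot_mesh(mesh)
  co <- face_corners(mesh)
  cent <- (co$a + co$b + co$c) / 3
  rad <- sqrt(cent[, 1]^2 + cent[, 2]^2) * mesh$unit_scale
  keep <- rad >= hub_radius
  if (!any(keep)) stop("no roots found outside the hub clearance")
  trimmed <- mesh
  trimmed$faces <- mesh$faces[keep, , drop = FALSE]
  comps <- connected_components(trimmed)
  segs <- list()
  for (cm in comps) {
    closed <- cap_boundary_holes(cm)
    vol <- abs(signed_volume(closed, check = FALSE))
    if (vol < min_volume) next
    # attachment: centroid of the hub-cut mouth (the cap nearest the axis)
    caps <- attr(closed, "cap_centroids")
    attach_pt <- if (!is.null(caps) && nrow(caps)) {
      caps[which.min(caps[, 1]^2 + caps[, 2]^2), ]
    } else {
      v <- closed$vertices
      v[which.min(v[, 1]^2 + v[, 2]^2), ]
    }
    seg <- structure(list(mesh = closed, volume = vol,
                          attachment_point = attach_pt,
                          hub_radius = hub_radius, fused = FALSE),
                     class = "root_segment")
    seg$fused <- is_fused_segment(seg)
    segs[[length(segs) + 1L]] <- seg
  }
  if (length(segs) == 0L) stop("no roots found above the volume threshold")
  segs
}

# Two roots merged into one surface betray themselves in cross-section:
# either several stations show two disjoint loops (roots that separate
# along the run), or the merged outline is strongly non-circular (a peanut
# profile; isoperimetric ratio P^2 / 4 pi A well above a lone root's).
is_fused_segment <- function(seg) {
  cl <- tryCatch(segment_centerline(seg, step = 2), error = function(e) NULL)
  if (is.null(cl)) return(FALSE)
  if (sum(cl$loop_counts >= 2) >= 3L) return(TRUE)
  m <- seg$mesh
  v <- m$vertices
  d0 <- stats::prcomp(v)$rotation[, 1]
  ctr <- colMeans(v)
  t <- as.vector(sweep(v, 2L, ctr) %*% d0)
  st <- seq(stats::quantile(t, 0.15), stats::quantile(t, 0.85),
            length.out = 7L)
  iso <- vapply(st, function(s0) {
    loops <- cross_section_loops(m, mesh_plane(ctr + s0 * d0, d0))
    if (!length(loops)) return(NA_real_)
    a <- sum(vapply(loops, `[[`, numeric(1), "area"))
    per <- sum(vapply(loops, function(L) {
      p <- L$points
      sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2)))
    }, numeric(1)))
    per^2 / (4 * pi * a)
  }, numeric(1))
  isTRUE(stats::median(iso, na.rm = TRUE) > 1.30)
}

#' Measure the centerline of a root segment
#'
#' Two-pass plane-slicing: cross-sections are first taken perpendicular to
#' the segment's principal axis, then re-sliced perpendicular to the local
#' tangent of the first-pass centroid polyline. The polyline is oriented to
#' start at the attachment (hub) end and extended axially to the mesh
#' extremes.
#'
#' @param seg a `root_segment`.
#' @param step slice spacing in cm.
#' @return list with `polyline` (k x 3), `length` (cm), `areas`
#'   (cross-section areas), `loop_counts` (loops per station).
#' @export
segment_centerline <- function(seg, step = 1) {
  m <- seg$mesh
  v <- m$vertices
  if (nrow(v) < 4L) stop("fewer than 2 valid cross-sections")
  d0 <- stats::prcomp(v)$rotation[, 1]
  t <- as.vector(sweep(v, 2L, colMeans(v)) %*% d0)
  rng <- range(t)
  if (diff(rng) < step) stop("fewer than 2 valid cross-sections")
  stations <- seq(rng[1] + step / 2, rng[2] - step / 2, by = step)
  if (length(stations) < 2L) stop("fewer than 2 valid cross-sections")
  ctr <- colMeans(v)
  slice_at <- function(point, dir) {
    loops <- cross_section_loops(m, mesh_plane(point, dir))
    if (length(loops) == 0L) return(NULL)
    w <- vapply(loops, `[[`, numeric(1), "area")
    cts <- t(vapply(loops, `[[`, numeric(3), "centroid"))
    list(centroid = colSums(cts * w) / sum(w), area = sum(w),
         count = length(loops))
  }
  # pass 1: slices perpendicular to the principal axis
  pass1 <- lapply(stations, function(s) slice_at(ctr + s * d0, d0))
  ok <- !vapply(pass1, is.null, logical(1))
  if (sum(ok) < 2L) stop("fewer than 2 valid cross-sections")
  c1 <- t(vapply(pass1[ok], `[[`, numeric(3), "centroid"))
  st1 <- stations[ok]
  # pass 2: re-slice perpendicular to the local tangent
  k <- nrow(c1)
  tangents <- matrix(0, k, 3L)
  for (i in seq_len(k)) {
    a <- max(1L, i - 2L); b <- min(k, i + 2L)
    tg <- c1[b, ] - c1[a, ]
    nn <- sqrt(sum(tg^2))
    tangents[i, ] <- if (nn > 1e-9) tg / nn else d0
  }
  pass2 <- lapply(seq_len(k), function(i) slice_at(c1[i, ], tangents[i, ]))
  ok2 <- !vapply(pass2, is.null, logical(1))
  if (sum(ok2) < 2L) stop("fewer than 2 valid cross-sections")
  c2 <- t(vapply(pass2[ok2], `[[`, numeric(3), "centroid"))
  areas <- vapply(pass2[ok2], `[[`, numeric(1), "area")
  counts <- vapply(pass2[ok2], `[[`, numeric(1), "count")
  # sections near the ends have centroids skewed by the end caps, and the
  # attachment end by the oblique hub-cut mouth (which runs further up the
  # root); trim those from the centerline polyline — the axial end
  # extension recovers the trimmed distance — but keep their areas
  med_r <- stats::median(sqrt(areas / pi))
  cut_tip <- max(step / 2, 0.9 * med_r)
  cut_base <- max(step / 2, 2.0 * med_r)
  st2 <- st1[ok2]
  basal_first <- is.null(seg$attachment_point) ||
    sum((c2[1, ] - seg$attachment_point)^2) <=
    sum((c2[nrow(c2), ] - seg$attachment_point)^2)
  lo <- rng[1] + if (basal_first) cut_base else cut_tip
  hi <- rng[2] - if (basal_first) cut_tip else cut_base
  keep <- st2 > lo & st2 < hi
  if (sum(keep) >= 2L) c2 <- c2[keep, , drop = FALSE]
  # orient from the attachment end outward
  if (!is.null(seg$attachment_point)) {
    if (sum((c2[1, ] - seg$attachment_point)^2) >
        sum((c2[nrow(c2), ] - seg$attachment_point)^2)) {
      c2 <- c2[rev(seq_len(nrow(c2))), , drop = FALSE]
      areas <- rev(areas); counts <- rev(counts)
    }
  }
  # drop end points whose step direction disagrees with the local run
  # (residual mouth or cap artefacts); genuine curvature at 1 cm steps is
  # well under the 7-degree threshold
  step_angle <- function(p, i, j) {
    a <- p[i + 1L, ] - p[i, ]; b <- p[j + 1L, ] - p[j, ]
    acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
  }
  for (side in 1:2) {
    drops <- 0L
    while (nrow(c2) >= 5L && drops < 4L &&
           step_angle(c2, 1L, 3L) > 7) {
      c2 <- c2[-1L, , drop = FALSE]; drops <- drops + 1L
    }
    c2 <- c2[rev(seq_len(nrow(c2))), , drop = FALSE]  # flip, clean other end
  }
  poly_len <- sum(sqrt(rowSums(diff(c2)^2)))
  # axial end extensions: outward to the extreme vertex at the tip, and to
  # the attachment point at the basal end (the far lip of an oblique hub
  # cut must not count as root length)
  k2 <- nrow(c2)
  tg_start <- c2[1, ] - c2[min(3L, k2), ]
  tg_start <- tg_start / max(sqrt(sum(tg_start^2)), 1e-12)
  tg_end <- c2[k2, ] - c2[max(1L, k2 - 2L), ]
  tg_end <- tg_end / max(sqrt(sum(tg_end^2)), 1e-12)
  ext_start <- if (!is.null(seg$hub_radius)) {
    # extend the basal tangent back to the hub clearance cylinder
    p <- c2[1, ]; dxy <- tg_start[1:2]
    a <- sum(dxy^2); b <- 2 * sum(p[1:2] * dxy)
    cc <- sum(p[1:2]^2) - seg$hub_radius^2
    disc <- b^2 - 4 * a * cc
    if (a > 1e-12 && disc >= 0) {
      ts <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      ts <- ts[ts > 0]
      if (length(ts)) min(ts) else 0
    } else if (!is.null(seg$attachment_point))
      sum((seg$attachment_point - p) * tg_start) else 0
  } else if (is.null(seg$attachment_point))
    max(as.vector(sweep(v, 2L, c2[1, ]) %*% tg_start))
  else sum((seg$attachment_point - c2[1, ]) * tg_start)
  ext_end <- max(as.vector(sweep(v, 2L, c2[k2, ]) %*% tg_end))
  total <- poly_len + min(max(0, ext_start), 4 * med_r + step) +
    max(0, ext_end)
  list(polyline = c2, length = total * m$unit_scale,
       areas = areas, loop_counts = counts)
}

#' Centerline length of a root segment
#'
#' @param seg a `root_segment`.
#' @param step slice spacing in cm.
#' @return length in cm.
#' @export
root_length <- function(seg, step = 1) {
  segment_centerline(seg, step)$length
}

#' Basal angle of a root segment
#'
#' Angle between the direction of the first quarter of the centerline
#' (starting at the attachment end) and the horizontal soil plane:
#' 0 = horizontal, 90 = straight down. Clamped to `[0, 90]`.
#'
#' @param seg a `root_segment`.
#' @param step slice spacing in cm.
#' @return angle in degrees.
#' @export
root_basal_angle <- function(seg, step = 1) {
  cl <- segment_centerline(seg, step)
  p <- cl$polyline
  seglen <- sqrt(rowSums(diff(p)^2))
  cum <- cumsum(seglen)
  i25 <- max(1L, which(cum >= 0.25 * sum(seglen))[1])
  d <- p[i25 + 1L, ] - p[1L, ]
  ang <- asin(abs(d[3]) / sqrt(sum(d^2))) * 180 / pi
  min(max(ang, 0), 90)
}

#' Maximum diameter of a root segment
#'
#' Maximum equivalent-circle diameter `2 * sqrt(area / pi)` over the
#' centerline cross-sections.
#'
#' @param seg a `root_segment`.
#' @param step slice spacing in cm.
#' @return diameter in cm.
#' @export
root_max_diameter <- function(seg, step = 1) {
  cl <- segment_centerline(seg, step)
  2 * sqrt(max(cl$areas) / pi)
}

#' Crown-level root angle
#'
#' Mean of the `k` smallest basal angles in the crown (the shallowest,
#' widest-spreading roots). With fewer than `k` roots all angles are
#' averaged, with a warning.
#'
#' @param angles numeric vector of per-root basal angles (degrees), or a
#'   list of `root_segment` objects.
#' @param k how many lowest angles to average (default 3).
#' @return angle in degrees.
#' @export
crown_root_angle <- function(angles, k = 3L) {
  if (is.list(angles))
    angles <- vapply(angles, root_basal_angle, numeric(1))
  if (length(angles) == 0L) stop("no root angles supplied")
  if (length(angles) < k) {
    warning(sprintf("only %d roots for a %d-lowest-angle summary; using all",
                    length(angles), k))
    return(mean(angles))
  }
  mean(sort(angles)[seq_len(k)])
}

#' Per-root summary table
#'
#' @param segs list of `root_segment` objects from [segment_roots()].
#' @param step slice spacing in cm.
#' @return data.frame with one row per root: length, basal angle, maximum
#'   diameter, volume, fused flag.
#' @export
summarize_segments <- function(segs, step = 1) {
  rows <- lapply(seq_along(segs), function(i) {
    seg <- segs[[i]]
    cl <- tryCatch(segment_centerline(seg, step), error = function(e) NULL)
    if (is.null(cl)) {
      return(data.frame(root_id = i, length_cm = NA_real_,
                        basal_angle_deg = NA_real_, max_diameter_cm = NA_real_,
                        volume_cm3 = seg$volume, fused = seg$fused))
    }
    p <- cl$polyline
    seglen <- sqrt(rowSums(diff(p)^2))
    cum <- cumsum(seglen)
    i25 <- max(1L, which(cum >= 0.25 * sum(seglen))[1])
    d <- p[i25 + 1L, ] - p[1L, ]
    ang <- min(max(asin(abs(d[3]) / sqrt(sum(d^2))) * 180 / pi, 0), 90)
    data.frame(root_id = i, length_cm = cl$length, basal_angle_deg = ang,
               max_diameter_cm = 2 * sqrt(max(cl$areas) / pi),
               volume_cm3 = seg$volume, fused = seg$fused)
  })
  do.call(rbind, rows)
}
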