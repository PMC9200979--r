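# ---------------------------------------------------------------------------
# Voxel machinery: the volume oracle (stand-in for water displacement) and
# the volumetric remesher behind close_holes().
# ---------------------------------------------------------------------------

# Grid covering the mesh bbox with a margin; origin is offset by irrational
# fractions of h so cell-centre rays never graze axis-aligned mesh edges.
# `snap` (list(axis, value)) forces one lattice plane to coincide with a
# given coordinate plane, so a flat cut lying there is represented exactly.
voxel_grid_spec <- function(mesh, h, snap = NULL) {
  b <- bbox_mesh(mesh)
  jit <- h * c(0.1234567891, 0.2345678912, 0.3456789123)
  origin <- b[1, ] - 2 * h - jit
  if (!is.null(snap)) {
    ax <- snap$axis
    origin[ax] <- origin[ax] + (snap$value - origin[ax]) %% h - h
  }
  dims <- as.integer(ceiling((b[2, ] - origin) / h)) + 2L
  list(origin = origin, h = h, dims = dims)
}

#' Voxel-oracle volume of a mesh
#'
#' Counts voxel centres enclosed by the surface (signed ray-crossing winding
#' along one axis) and returns `count * h^3 * unit_scale^3`. For a closed,
#' outward-oriented mesh — including unions of overlapping closed components,
#' as produced by the synthetic-crown generator — this converges to the true
#' enclosed volume as `h` shrinks. It is the package's independent ground
#' truth, standing in for water displacement.
#'
#' @param mesh a closed `triangle_mesh` (components may overlap).
#' @param h voxel edge length in model units (default 0.1, i.e. 1 mm when
#'   the mesh is in cm).
#' @param axis ray direction, 1 = x, 2 = y, 3 = z.
#' @return volume in cm^3.
#' @export
voxel_volume <- function(mesh, h = 0.1, axis = 3L) {
  stopifnot_mesh(mesh)
  g <- voxel_grid_spec(mesh, h)
  n <- voxel_inside_count_cpp(mesh$vertices, mesh$faces - 1L, g$origin, h,
                              g$dims, as.integer(axis) - 1L)
  n * h^3 * mesh$unit_scale^3
}

# occupancy by majority vote over ray directions; robust to open defects
occupancy_grid <- function(mesh, h, axes = 1:3, snap = NULL) {
  g <- voxel_grid_spec(mesh, h, snap = snap)
  votes <- occupancy_votes_cpp(mesh$vertices, mesh$faces - 1L, g$origin, h,
                               g$dims, as.integer(axes) - 1L)
  need <- floor(length(axes) / 2) + 1L
  occ <- array(votes >= need, dim = g$dims)
  list(occ = occ, origin = g$origin, h = h)
}

# Extract the boundary surface of an occupancy grid as a watertight,
# consistently outward-oriented quad mesh (split into triangles). Vertices
# sit on lattice corners.
occupancy_isosurface <- function(occ, origin, h, unit_scale = 1, label = "") {
  d <- dim(occ)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # pad with FALSE so boundary cells emit faces
  corner_id <- function(i, j, k)  # 1-based lattice corner -> linear id
    as.double(i) + (nx + 1) * (as.double(j) - 1) + (nx + 1) * (ny + 1) * (as.double(k) - 1)

  quads <- list(); qn <- 0L
  add_quads <- function(ci, cj, ck, axis, positive) {
    # face of cell (ci,cj,ck) on its +axis (positive) or -axis side,
    # wound so the normal points away from the occupied cell
    n <- length(ci)
    if (n == 0L) return()
    if (axis == 1L) {
      x <- ci + if (positive) 1L else 0L
      c1 <- corner_id(x, cj,     ck)
      c2 <- corner_id(x, cj + 1, ck)
      c3 <- corner_id(x, cj + 1, ck + 1)
      c4 <- corner_id(x, cj,     ck + 1)
      q <- if (positive) cbind(c1, c2, c3, c4) else cbind(c1, c4, c3, c2)
    } else if (axis == 2L) {
      y <- cj + if (positive) 1L else 0L
      c1 <- corner_id(ci,     y, ck)
      c2 <- corner_id(ci,     y, ck + 1)
      c3 <- corner_id(ci + 1, y, ck + 1)
      c4 <- corner_id(ci + 1, y, ck)
      q <- if (positive) cbind(c1, c2, c3, c4) else cbind(c1, c4, c3, c2)
    } else {
      z <- ck + if (positive) 1L else 0L
      c1 <- corner_id(ci,     cj,     z)
      c2 <- corner_id(ci + 1, cj,     z)
      c3 <- corner_id(ci + 1, cj + 1, z)
      c4 <- corner_id(ci,     cj + 1, z)
      q <- if (positive) cbind(c1, c2, c3, c4) else cbind(c1, c4, c3, c2)
    }
    qn <<- qn + 1L
    quads[[qn]] <<- q
  }

  idx_grid <- function(mask) which(mask, arr.ind = TRUE)
  for (ax in 1:3) {
    # abind_shift(occ, ax, +1) holds the neighbour at -1, and vice versa
    face_lo <- occ & !abind_shift(occ, ax, +1L)  # neighbour below empty
    face_hi <- occ & !abind_shift(occ, ax, -1L)  # neighbour above empty
    w <- idx_grid(face_lo); add_quads(w[, 1], w[, 2], w[, 3], ax, FALSE)
    w <- idx_grid(face_hi); add_quads(w[, 1], w[, 2], w[, 3], ax, TRUE)
  }

  if (qn == 0L) stop("no enclosed volume")
  allq <- do.call(rbind, quads)
  used <- sort(unique(as.vector(allq)))
  map_pos <- match(as.vector(allq), used)
  fq <- matrix(map_pos, ncol = 4L)
  # lattice corner id -> coordinates
  id0 <- used - 1
  i <- id0 %% (nx + 1)
  j <- (id0 %/% (nx + 1)) %% (ny + 1)
  k <- id0 %/% ((nx + 1) * (ny + 1))
  verts <- cbind(origin[1] + i * h, origin[2] + j * h, origin[3] + k * h)
  faces <- rbind(fq[, c(1, 2, 3)], fq[, c(1, 3, 4)])
  triangle_mesh(verts, faces, unit_scale, label)
}

# One-cell morphological closing (6-neighbourhood dilation then erosion).
# Smooth volumetric remeshers cannot represent gaps narrower than their cell
# size: slits between crowded roots and small surface defects are fused
# shut. Closing reproduces that behaviour — and with it the documented
# inflation of intact-crown volumes that the split-half protocol reduces
# (each half is rebuilt on its own, finer grid).
morph_close <- function(occ, radius = 2L) {
  grow <- function(a) {
    a | abind_shift(a, 1L, +1L) | abind_shift(a, 1L, -1L) |
      abind_shift(a, 2L, +1L) | abind_shift(a, 2L, -1L) |
      abind_shift(a, 3L, +1L) | abind_shift(a, 3L, -1L)
  }
  shrink <- function(a) {
    a & abind_shift(a, 1L, +1L) & abind_shift(a, 1L, -1L) &
      abind_shift(a, 2L, +1L) & abind_shift(a, 2L, -1L) &
      abind_shift(a, 3L, +1L) & abind_shift(a, 3L, -1L)
  }
  for (k in seq_len(radius)) occ <- grow(occ)
  for (k in seq_len(radius)) occ <- shrink(occ)
  occ
}

# Resolve "hinge" configurations (two occupied cells meeting only along an
# edge) by filling one of the empty face-neighbours; otherwise the extracted
# surface has edges shared by four faces and fails the strict edge-manifold
# test. Usually converges in one or two sweeps.
fill_hinges <- function(occ, max_iter = 8L) {
  nb <- function(a, axis) abind_shift(a, axis, -1L)   # neighbour at +1
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      a1 <- pair[1]; a2 <- pair[2]
      n1 <- nb(occ, a1); n2 <- nb(occ, a2); n12 <- nb(nb(occ, a1), a2)
      m1 <- occ & n12 & !n1 & !n2          # diagonal A=(0,0), B=(1,1)
      m2 <- !occ & n1 & n2 & !n12          # diagonal A=(1,0), B=(0,1)
      if (any(m1)) { occ <- occ | abind_shift(m1, a1, +1L); changed <- TRUE }
      if (any(m2)) { occ[m2] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  occ
}

# shift a 3D logical array by one cell along `axis`; vacated cells FALSE
abind_shift <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else        { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Taubin smoothing
#'
#' Two-pass Laplacian smoothing (positive then negative weight) that relaxes
#' the staircase of a voxel-extracted surface while approximately preserving
#' volume. Used by [close_holes()].
#'
#' @param mesh a `triangle_mesh`.
#' @param iterations number of lambda/mu passes.
#' @param lambda positive smoothing weight.
#' @param mu negative (inflation) weight.
#' @return smoothed `triangle_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 5L, lambda = 0.33, mu = -0.34) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- (as.double(lo) - 1) * nrow(mesh$vertices) + hi
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]
  nv <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  P <- mesh$vertices
  for (it in seq_len(iterations)) {
    P <- P + lambda * (as.matrix(W %*% P) - P)
    P <- P + mu * (as.matrix(W %*% P) - P)
  }
  mesh$vertices <- P
  mesh
}
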