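# ---------------------------------------------------------------------------
# Parametric closed meshes: box, icosphere, tube/frustum. Used as fixtures
# and as building blocks of the synthetic-crown generator.
# ---------------------------------------------------------------------------

#' Axis-aligned box mesh
#'
#' @param dims 3-vector of edge lengths.
#' @param center 3-vector box centre.
#' @return watertight `triangle_mesh` (12 triangles).
#' @export
box_mesh <- function(dims = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- dims / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8L), 2L, -center)
  # corners: 1=(---) 2=(+--) 3=(-+-) 4=(++-) 5=(--+) 6=(+-+) 7=(-++) 8=(+++)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7),   # z = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 7, 8), c(3, 8, 4),   # y = +h
    c(1, 5, 7), c(1, 7, 3),   # x = -h
    c(2, 4, 8), c(2, 8, 6))   # x = +h
  triangle_mesh(v, f, label = "box")
}

#' Unit cube mesh
#' @return watertight `triangle_mesh` of the cube `[0,1]^3`.
#' @export
unit_cube_mesh <- function() {
  m <- box_mesh(c(1, 1, 1), center = c(0.5, 0.5, 0.5))
  m$label <- "unit cube"
  m
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected onto
#' the sphere.
#'
#' @param radius sphere radius.
#' @param subdivisions number of 1-to-4 subdivision rounds.
#' @param center 3-vector centre.
#' @return watertight `triangle_mesh`.
#' @export
icosphere_mesh <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdivisions)) {
    nv <- nrow(v)
    mid_env <- new.env(parent = emptyenv())
    vlist <- list(); vn <- 0L
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      id <- mid_env[[key]]
      if (!is.null(id)) return(id)
      vn <<- vn + 1L
      vlist[[vn]] <<- (v[i, ] + v[j, ]) / 2
      id <- nv + vn
      mid_env[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, vlist))
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  m <- triangle_mesh(v, f, label = "icosphere")
  if (signed_volume(m, check = FALSE) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  v <- sweep(m$vertices, 2L, -center)
  triangle_mesh(v, m$faces, label = "icosphere")
}

#' Tube mesh along a polyline centerline
#'
#' Sweeps a circle of (per-station) radius along a centerline, producing a
#' closed tube with flat end caps. This is the building block for synthetic
#' storage roots (tapered, possibly curved frusta) and stem cylinders.
#'
#' @param centerline k x 3 matrix of centerline points (k >= 2).
#' @param radii vector of k radii (recycled if length 1).
#' @param n_around vertices around the circumference.
#' @return watertight `triangle_mesh`.
#' @export
tube_mesh <- function(centerline, radii, n_around = 12L) {
  p <- as.matrix(centerline)
  k <- nrow(p)
  if (k < 2L) stop("centerline needs at least 2 points")
  radii <- rep_len(radii, k)
  if (any(radii <= 0)) stop("radii must be positive")
  # parallel-transported frames along the polyline
  tangent <- function(i) {
    d <- if (i == 1L) p[2, ] - p[1, ] else if (i == k) p[k, ] - p[k - 1, ]
         else p[i + 1, ] - p[i - 1, ]
    d / sqrt(sum(d^2))
  }
  t1 <- tangent(1L)
  e1 <- plane_basis(t1)[, 1]
  theta <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  verts <- matrix(0, k * n_around + 2L, 3L)
  prev_t <- t1; prev_e <- e1
  for (i in seq_len(k)) {
    ti <- tangent(i)
    # rotate previous frame onto the new tangent (minimal rotation)
    cthe <- sum(prev_t * ti)
    if (cthe < 0.999999) {
      ax <- c(prev_t[2] * ti[3] - prev_t[3] * ti[2],
              prev_t[3] * ti[1] - prev_t[1] * ti[3],
              prev_t[1] * ti[2] - prev_t[2] * ti[1])
      s <- sqrt(sum(ax^2))
      if (s > 1e-12) {
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                    3, 3, byrow = TRUE)
        R <- diag(3) + K + K %*% K * ((1 - cthe) / s^2)
        prev_e <- as.vector(R %*% prev_e)
      }
    }
    prev_t <- ti
    e1i <- prev_e - sum(prev_e * ti) * ti
    e1i <- e1i / sqrt(sum(e1i^2))
    e2i <- c(ti[2] * e1i[3] - ti[3] * e1i[2], ti[3] * e1i[1] - ti[1] * e1i[3],
             ti[1] * e1i[2] - ti[2] * e1i[1])
    ring <- p[rep(i, n_around), ] +
      radii[i] * (outer(cos(theta), e1i) + outer(sin(theta), e2i))
    verts[(i - 1L) * n_around + seq_len(n_around), ] <- ring
    prev_e <- e1i
  }
  base_c <- k * n_around + 1L
  tip_c <- k * n_around + 2L
  verts[base_c, ] <- p[1, ]
  verts[tip_c, ] <- p[k, ]
  faces <- list(); fi <- 0L
  ring_idx <- function(i) (i - 1L) * n_around + seq_len(n_around)
  for (i in seq_len(k - 1L)) {
    r0 <- ring_idx(i); r1 <- ring_idx(i + 1L)
    nx <- c(seq_len(n_around)[-1L], 1L)
    fi <- fi + 1L
    faces[[fi]] <- cbind(r0, r1[nx], r1)
    fi <- fi + 1L
    faces[[fi]] <- cbind(r0, r0[nx], r1[nx])
  }
  r0 <- ring_idx(1L); rk <- ring_idx(k)
  nx <- c(seq_len(n_around)[-1L], 1L)
  fi <- fi + 1L; faces[[fi]] <- cbind(base_c, r0[nx], r0)      # base cap
  fi <- fi + 1L; faces[[fi]] <- cbind(tip_c, rk, rk[nx])       # tip cap
  triangle_mesh(verts, do.call(rbind, faces), label = "tube")
}

#' Right circular cylinder mesh
#' @param radius cylinder radius.
#' @param height cylinder height (along +z from `base`).
#' @param base 3-vector of the base-centre position.
#' @param n_around circumferential resolution.
#' @param n_axial axial stations.
#' @return watertight `triangle_mesh`.
#' @export
cylinder_mesh <- function(radius, height, base = c(0, 0, 0), n_around = 24L,
                          n_axial = 2L) {
  z <- seq(0, height, length.out = max(2L, n_axial))
  ctr <- cbind(base[1], base[2], base[3] + z)
  m <- tube_mesh(ctr, radius, n_around)
  m$label <- "cylinder"
  m
}

#' Conical frustum mesh
#' @param r_base basal radius.
#' @param r_tip tip radius.
#' @param length axial length (along +x from the origin by default).
#' @param axis direction of the frustum axis.
#' @param base 3-vector of the base-centre position.
#' @param n_around circumferential resolution.
#' @param n_axial axial stations.
#' @return watertight `triangle_mesh`.
#' @export
frustum_mesh <- function(r_base, r_tip, length, axis = c(1, 0, 0),
                         base = c(0, 0, 0), n_around = 24L, n_axial = 16L) {
  axis <- axis / sqrt(sum(axis^2))
  t <- seq(0, 1, length.out = max(2L, n_axial))
  ctr <- sweep(outer(t * length, axis), 2L, -base)
  m <- tube_mesh(ctr, r_base + t * (r_tip - r_base), n_around)
  m$label <- "frustum"
  m
}
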