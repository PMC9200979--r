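#' @useDynLib crc3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif prcomp sd var
NULL

# ---------------------------------------------------------------------------
# TriangleMesh: the universal carrier for crowns, roots and reference objects.
# vertices: n x 3 numeric matrix (model units; cm once unit_scale == 1 after
# calibration); faces: m x 3 integer matrix of 1-based vertex indices with
# consistent outward orientation; unit_scale: physical cm per model unit.
# ---------------------------------------------------------------------------

#' Construct a triangle mesh
#'
#' Creates a `triangle_mesh` object, the carrier used throughout the package
#' for crowns, individual storage roots and reference objects. Faces are
#' 1-based index triples; an outward, consistent orientation is assumed by
#' the volume routines. Degenerate (zero-area) faces are removed.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), in model units.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param unit_scale physical length (cm) represented by one model unit.
#' @param label free-text provenance label.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, unit_scale = 1.0, label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must have 3 columns")
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face index out of range: faces must reference existing vertices")
  }
  m <- structure(
    list(vertices = vertices, faces = faces,
         unit_scale = as.numeric(unit_scale), label = as.character(label)),
    class = "triangle_mesh")
  drop_degenerate_faces(m)
}

# remove zero-area faces (area < 1e-12 model-units^2) and repeated indices
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(mesh)
  dup <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  a <- triangle_areas(mesh)
  bad <- dup | a < tol
  if (any(bad)) mesh$faces <- f[!bad, , drop = FALSE]
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, unit_scale = %g cm/unit%s\n",
              nrow(x$vertices), nrow(x$faces), x$unit_scale,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
is_empty_mesh <- function(mesh) nrow(mesh$faces) == 0L || nrow(mesh$vertices) == 0L

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) stop("not a triangle_mesh")
  if (is_empty_mesh(mesh)) stop("empty mesh")
  invisible(mesh)
}

# per-face corner coordinate arrays; used by most geometric routines
face_corners <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-triangle areas (model units squared)
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of triangle areas.
#' @keywords internal
triangle_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(numeric(0))
  co <- face_corners(mesh)
  n <- cross3(co$b - co$a, co$c - co$a)
  0.5 * sqrt(rowSums(n * n))
}

#' Plane through a point
#'
#' A plane is stored as a base point and a unit normal; it is the carrier for
#' all cutting operations (stem removal, the split-half protocol).
#'
#' @param point 3-vector on the plane.
#' @param normal 3-vector; normalised internally.
#' @return An object of class `mesh_plane`.
#' @export
mesh_plane <- function(point, normal) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-300) stop("plane normal must be non-zero")
  structure(list(point = as.numeric(point), normal = normal / nn),
            class = "mesh_plane")
}

# ---------------------------------------------------------------------------
# I/O: Wavefront OBJ and ascii PLY, positions + faces only.
# ---------------------------------------------------------------------------

#' Read a triangle mesh from OBJ or PLY
#'
#' Parses vertex positions and polygonal faces; normals, texture coordinates
#' and colours are discarded. Polygons with more than three sides are fan
#' triangulated. Vertices closer than `1e-9` model units are merged.
#' The returned mesh is uncalibrated (`unit_scale = 1`).
#'
#' @param path file path.
#' @param format `"obj"` or `"ply"`; guessed from the extension by default.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("obj", "ply")) ext else
      stop("cannot guess mesh format from extension: ", path)
  }
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  m <- switch(format, obj = read_obj(path), ply = read_ply(path))
  m <- dedupe_vertices(m)
  if (is_empty_mesh(m)) stop("empty mesh (zero faces): ", path)
  m
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines_idx <- grep("^f\\s", lines)
  if (length(vlines) == 0L || length(flines_idx) == 0L)
    stop("OBJ format error: no vertex or face records in ", path)
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) stop("OBJ format error: bad vertex line '",
                         paste(tok, collapse = " "), "'")
    xyz
  }, numeric(3)))
  nv <- nrow(verts)
  faces_list <- vector("list", length(flines_idx))
  for (k in seq_along(flines_idx)) {
    ln <- lines[flines_idx[k]]
    tok <- strsplit(trimws(ln), "\\s+")[[1]][-1]
    # each token may be i, i/t, i/t/n or i//n; keep the vertex index
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (anyNA(idx)) stop("OBJ format error at line ", flines_idx[k], ": '", ln, "'")
    if (any(idx == 0L)) stop("OBJ format error at line ", flines_idx[k],
                             ": OBJ vertex indices are 1-based, found 0 in '", ln, "'")
    if (any(idx < 0L)) idx[idx < 0L] <- nv + 1L + idx[idx < 0L]
    if (any(idx < 1L | idx > nv)) stop("OBJ format error at line ", flines_idx[k],
                                       ": vertex index out of range in '", ln, "'")
    if (length(idx) < 3L) stop("OBJ format error at line ", flines_idx[k],
                               ": face with fewer than 3 vertices")
    faces_list[[k]] <- fan_triangulate(idx)
  }
  triangle_mesh(verts, do.call(rbind, faces_list), unit_scale = 1.0,
                label = basename(path))
}

fan_triangulate <- function(idx) {
  n <- length(idx)
  if (n == 3L) return(matrix(idx, 1L, 3L))
  cbind(idx[1L], idx[2:(n - 1L)], idx[3:n])
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop("PLY format error: missing 'ply' magic in ", path)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("PLY format error: no end_header in ", path)
  hdr <- trimws(lines[seq_len(end_hdr)])
  if (!any(grepl("^format ascii", hdr)))
    stop("PLY format error: only ascii PLY is supported (", path, ")")
  el <- grep("^element ", hdr, value = TRUE)
  counts <- list()
  for (e in el) {
    tok <- strsplit(e, "\\s+")[[1]]
    counts[[tok[2]]] <- as.integer(tok[3])
  }
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  if (is.null(nv) || is.null(nf)) stop("PLY format error: need vertex and face elements")
  body <- lines[(end_hdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("PLY format error: truncated body in ", path)
  verts <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                    function(tok) as.numeric(tok[1:3]), numeric(3)))
  faces_list <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), function(tok) {
    k <- as.integer(tok[1])
    idx <- as.integer(tok[2:(k + 1L)]) + 1L  # PLY is 0-based
    if (anyNA(idx) || any(idx < 1L) || any(idx > nv))
      stop("PLY format error: face index out of range")
    fan_triangulate(idx)
  })
  triangle_mesh(verts, do.call(rbind, faces_list), unit_scale = 1.0,
                label = basename(path))
}

dedupe_vertices <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3L)
  triangle_mesh(newv, newf, mesh$unit_scale, mesh$label)
}

#' Write a triangle mesh to OBJ or PLY
#'
#' @param mesh a non-empty `triangle_mesh`.
#' @param path output file path.
#' @param format `"obj"` or `"ply"`; guessed from the extension by default.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply")) {
  stopifnot_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("obj", "ply")) ext else
      stop("cannot guess mesh format from extension: ", path)
  }
  v <- mesh$vertices; f <- mesh$faces
  txt <- if (format == "obj") {
    c("# crc3d mesh export",
      sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else {
    c("ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Closed-surface geometry
# ---------------------------------------------------------------------------

#' Signed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedra spanned by the origin and each
#' face, multiplied by `unit_scale^3`. Positive for a closed mesh with
#' outward-oriented faces. For a mesh made of several disjoint closed
#' components the result is the sum of component volumes (overlapping
#' regions are counted once per enclosing surface).
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param check if `TRUE` (default) error on a non-watertight mesh.
#' @return volume in cm^3.
#' @export
signed_volume <- function(mesh, check = TRUE) {
  stopifnot_mesh(mesh)
  if (check && !is_watertight(mesh))
    stop("mesh is not watertight; close it first with close_holes()")
  co <- face_corners(mesh)
  v6 <- rowSums(co$a * cross3(co$b, co$c))
  sum(v6) / 6 * mesh$unit_scale^3
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas times `unit_scale^2`.
#'
#' @param mesh a non-empty `triangle_mesh`.
#' @return area in cm^2.
#' @export
surface_area <- function(mesh) {
  stopifnot_mesh(mesh)
  sum(triangle_areas(mesh)) * mesh$unit_scale^2
}

# undirected edge keys for each face edge; nv-based integer encoding
edge_keys <- function(faces, nv) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  (as.double(lo) - 1) * nv + as.double(hi)
}

#' Test whether a mesh is watertight
#'
#' Strict edge-manifold test: every undirected edge must be shared by exactly
#' two faces. A union of disjoint closed components is watertight in this
#' sense even if the components overlap geometrically.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  if (is_empty_mesh(mesh)) return(FALSE)
  keys <- edge_keys(mesh$faces, nrow(mesh$vertices))
  all(tabulate(match(keys, unique(keys))) == 2L)
}

#' Directed boundary edges (edges used by exactly one face)
#' @keywords internal
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  nv <- nrow(mesh$vertices)
  keys <- (pmin(e[, 1], e[, 2]) - 1) * as.double(nv) + pmax(e[, 1], e[, 2])
  cnt <- table(keys)
  single <- names(cnt)[cnt == 1L]
  e[keys %in% as.double(single), , drop = FALSE]
}

#' Split a mesh into connected components
#'
#' Faces are grouped by edge connectivity (faces sharing an edge are
#' connected; sharing a single vertex is not enough). Total face count is
#' conserved across the returned parts.
#'
#' @param mesh a `triangle_mesh`.
#' @return list of `triangle_mesh`, largest (by face count) first.
#' @export
connected_components <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  nf <- nrow(f)
  keys <- edge_keys(f, nrow(mesh$vertices))
  fid <- rep.int(seq_len(nf), 3L)
  grp <- split(fid, keys)
  grp <- grp[lengths(grp) > 1L]
  if (length(grp)) {
    pairs <- do.call(rbind, lapply(grp, function(g) cbind(g[1L], g[-1L])))
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nf - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_len(nf)]
  } else memb <- seq_len(nf)
  parts <- split(seq_len(nf), memb)
  parts <- parts[order(-lengths(parts))]
  unname(lapply(parts, function(ix) submesh(mesh, ix)))
}

# extract the faces `face_idx` as a standalone mesh with compacted vertices
submesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(map[f], ncol = 3L), mesh$unit_scale, mesh$label)
}

# merge several meshes into one (disjoint union of face sets)
merge_meshes <- function(meshes, label = "") {
  meshes <- meshes[!vapply(meshes, is_empty_mesh, logical(1))]
  if (length(meshes) == 0L) stop("no non-empty meshes to merge")
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), integer(1))))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, lapply(seq_along(meshes),
                                 function(i) meshes[[i]]$faces + offs[i]))
  triangle_mesh(verts, faces, meshes[[1]]$unit_scale, label)
}

# rigid / affine helpers --------------------------------------------------

#' Apply a rotation (and optional translation) to a mesh
#' @param mesh a `triangle_mesh`.
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector added after rotation.
#' @return transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2L, -translation)
  mesh
}

#' Uniformly scale mesh coordinates
#' @param mesh a `triangle_mesh`.
#' @param s scale factor applied to all vertex coordinates.
#' @return scaled `triangle_mesh` (unit_scale unchanged).
#' @export
scale_mesh <- function(mesh, s) {
  mesh$vertices <- mesh$vertices * s
  mesh
}

bbox_mesh <- function(mesh) {
  rbind(apply(mesh$vertices, 2L, min), apply(mesh$vertices, 2L, max))
}

bbox_diagonal <- function(mesh) {
  b <- bbox_mesh(mesh)
  sqrt(sum((b[2, ] - b[1, ])^2))
}

# ---------------------------------------------------------------------------
# Plane cut with polygonal caps
# ---------------------------------------------------------------------------

#' Cut a watertight mesh with a plane
#'
#' Splits the mesh into the part below the plane (signed distance < 0) and
#' the part above it. Crossing triangles are clipped exactly; each resulting
#' cross-section boundary loop is capped by ear-clipping, so both outputs
#' are closed and their signed volumes sum to the input volume. Annular
#' cross-sections are handled by the inherited loop orientation.
#'
#' @param mesh a watertight `triangle_mesh`.
#' @param plane a `mesh_plane`.
#' @return list with elements `below` and `above` (`triangle_mesh` or `NULL`
#'   when the plane misses the mesh on that side).
#' @export
plane_cut <- function(mesh, plane) {
  stopifnot_mesh(mesh)
  if (!is_watertight(mesh))
    stop("plane_cut requires a watertight mesh; close it first with close_holes()")
  parts <- partition_by_plane(mesh, plane, cap = TRUE)
  list(below = parts$below, above = parts$above)
}

# Core clipper. cap = FALSE leaves the cut open (used by the split-half
# protocol, which re-closes each half volumetrically).
partition_by_plane <- function(mesh, plane, cap = TRUE) {
  v <- mesh$vertices
  n <- plane$normal
  d <- as.vector(v %*% n) - sum(plane$point * n)
  eps <- 1e-9 * max(1, bbox_diagonal(mesh))
  d[abs(d) < eps] <- eps  # nudge on-plane vertices to the positive side
  f <- mesh$faces
  s <- matrix(d[f] > 0, ncol = 3L)
  npos <- rowSums(s)
  below_only <- npos == 0L
  above_only <- npos == 3L
  mixed <- which(npos == 1L | npos == 2L)

  if (length(mixed) == 0L) {
    below <- if (any(below_only)) submesh(mesh, which(below_only)) else NULL
    above <- if (any(above_only)) submesh(mesh, which(above_only)) else NULL
    return(list(below = below, above = above))
  }

  nv <- nrow(v)
  # crossing point per unique crossing mesh edge
  new_pts <- new.env(parent = emptyenv())
  pt_list <- list(); pt_n <- 0L
  get_cross <- function(i, j) {
    key <- paste0(min(i, j), "_", max(i, j))
    id <- new_pts[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    pt_n <<- pt_n + 1L
    pt_list[[pt_n]] <<- p
    id <- nv + pt_n
    new_pts[[key]] <- id
    id
  }

  below_faces <- list(); above_faces <- list()
  bi <- 0L; ai <- 0L
  # directed cut edges per side (vertex-id pairs)
  cutb <- list(); cb <- 0L
  cuta <- list(); ca <- 0L

  for (k in mixed) {
    idx <- f[k, ]; sg <- d[idx] > 0
    polyb <- integer(0); polya <- integer(0)
    crossings <- integer(0)
    for (e in 1:3) {
      i <- idx[e]; j <- idx[if (e == 3L) 1L else e + 1L]
      if (!sg[e]) polyb <- c(polyb, i) else polya <- c(polya, i)
      if (xor(sg[e], d[j] > 0)) {
        x <- get_cross(i, j)
        polyb <- c(polyb, x); polya <- c(polya, x)
        crossings <- c(crossings, x)
      }
    }
    # record the directed plane-lying edge of each side polygon
    cutb_edge <- poly_plane_edge(polyb, crossings)
    cuta_edge <- poly_plane_edge(polya, crossings)
    if (!is.null(cutb_edge)) { cb <- cb + 1L; cutb[[cb]] <- cutb_edge }
    if (!is.null(cuta_edge)) { ca <- ca + 1L; cuta[[ca]] <- cuta_edge }
    for (tr in fan_poly(polyb)) { bi <- bi + 1L; below_faces[[bi]] <- tr }
    for (tr in fan_poly(polya)) { ai <- ai + 1L; above_faces[[ai]] <- tr }
  }

  allv <- rbind(v, do.call(rbind, pt_list))
  fb <- rbind(f[below_only, , drop = FALSE], do.call(rbind, below_faces))
  fa <- rbind(f[above_only, , drop = FALSE], do.call(rbind, above_faces))

  if (cap) {
    capb <- cap_loops(allv, do.call(rbind, cutb), plane)
    capa <- cap_loops(allv, do.call(rbind, cuta), plane)
    fb <- rbind(fb, capb)
    fa <- rbind(fa, capa)
  }
  below <- if (nrow(fb)) compact_mesh(allv, fb, mesh) else NULL
  above <- if (nrow(fa)) compact_mesh(allv, fa, mesh) else NULL
  list(below = below, above = above)
}

compact_mesh <- function(allv, faces, parent) {
  used <- sort(unique(as.vector(faces)))
  map <- integer(nrow(allv)); map[used] <- seq_along(used)
  triangle_mesh(allv[used, , drop = FALSE], matrix(map[faces], ncol = 3L),
                parent$unit_scale, parent$label)
}

# in a clipped side polygon the two crossing ids are cyclically adjacent;
# return the directed edge (from -> to) lying in the cut plane
poly_plane_edge <- function(poly, crossings) {
  if (length(crossings) != 2L || length(poly) < 3L) return(NULL)
  np <- length(poly)
  for (e in seq_len(np)) {
    i <- poly[e]; j <- poly[if (e == np) 1L else e + 1L]
    if (i %in% crossings && j %in% crossings) return(c(i, j))
  }
  NULL
}

fan_poly <- function(poly) {
  np <- length(poly)
  if (np < 3L) return(list())
  lapply(seq_len(np - 2L), function(i) poly[c(1L, i + 1L, i + 2L)])
}

# chain directed cut edges into loops, reverse them (cap winding must oppose
# the piece boundary), project into the plane and ear-clip
cap_loops <- function(allv, edges, plane) {
  if (is.null(edges) || nrow(edges) == 0L) return(matrix(integer(0), 0L, 3L))
  nxt <- split(edges[, 2], edges[, 1])
  nxt <- vapply(nxt, `[[`, numeric(1), 1L)  # one outgoing edge per vertex id
  visited <- new.env(parent = emptyenv())
  loops <- list(); nl <- 0L
  for (st in edges[, 1]) {
    if (!is.null(visited[[as.character(st)]])) next
    loop <- st; cur <- st
    repeat {
      visited[[as.character(cur)]] <- TRUE
      nx <- nxt[[as.character(cur)]]
      if (is.null(nx) || is.na(nx)) { loop <- NULL; break }
      if (nx == st) break
      if (!is.null(visited[[as.character(nx)]])) { loop <- NULL; break }
      loop <- c(loop, nx); cur <- nx
    }
    if (!is.null(loop) && length(loop) >= 3L) { nl <- nl + 1L; loops[[nl]] <- loop }
  }
  if (nl == 0L) return(matrix(integer(0), 0L, 3L))
  basis <- plane_basis(plane$normal)
  out <- list(); oi <- 0L
  for (loop in loops) {
    loop <- rev(loop)  # cap faces oppose the directed boundary
    p2 <- sweep(allv[loop, , drop = FALSE], 2L, plane$point) %*% basis
    tris <- ear_clip(p2)
    if (nrow(tris)) { oi <- oi + 1L; out[[oi]] <- matrix(loop[tris], ncol = 3L) }
  }
  if (oi == 0L) return(matrix(integer(0), 0L, 3L))
  do.call(rbind, out)
}

plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  cbind(e1, e2)
}

# Close every boundary loop with a fan to its centroid. Topological repair
# for ragged (non-planar) hole mouths, e.g. after the hub clearance cut in
# root dissection; volumetric accuracy is the caller's concern.
cap_boundary_holes <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  nv0 <- nrow(mesh$vertices)
  keys <- (pmin(e[, 1], e[, 2]) - 1) * as.double(nv0) + pmax(e[, 1], e[, 2])
  cnt <- tabulate(match(keys, unique(keys)))
  names(cnt) <- unique(keys)
  bdry <- e[cnt[as.character(keys)] == 1L, , drop = FALSE]
  if (nrow(bdry) == 0L) return(mesh)
  nxt <- bdry[, 2]; names(nxt) <- bdry[, 1]
  visited <- logical(max(bdry))
  verts <- mesh$vertices
  faces_new <- list(); fi <- 0L
  for (st in bdry[, 1]) {
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
    ctr <- colMeans(verts[loop, , drop = FALSE])
    verts <- rbind(verts, ctr)
    cid <- nrow(verts)
    np <- length(loop)
    nx_i <- c(seq_len(np)[-1L], 1L)
    # cap triangles oppose the directed boundary edges (a -> b): use (c, b, a)
    fi <- fi + 1L
    faces_new[[fi]] <- cbind(cid, loop[nx_i], loop)
  }
  if (fi == 0L) return(mesh)
  out <- triangle_mesh(verts, rbind(f, do.call(rbind, faces_new)),
                       mesh$unit_scale, mesh$label)
  attr(out, "cap_centroids") <- verts[(nv0 + 1L):nrow(verts), , drop = FALSE]
  out
}

# ear clipping of a 2D polygon given in loop order; returns index triples
# into the input rows, wound in loop orientation
ear_clip <- function(p2) {
  n <- nrow(p2)
  if (n < 3L) return(matrix(integer(0), 0L, 3L))
  if (n == 3L) return(matrix(1:3, 1L, 3L))
  idx <- seq_len(n)
  area2 <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  orient <- sum(vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    p2[i, 1] * p2[j, 2] - p2[j, 1] * p2[i, 2]
  }, numeric(1)))
  o <- sign(orient); if (o == 0) o <- 1
  tris <- matrix(integer(0), 0L, 3L)
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (e in seq_len(m)) {
      i0 <- idx[if (e == 1L) m else e - 1L]
      i1 <- idx[e]
      i2 <- idx[if (e == m) 1L else e + 1L]
      a <- p2[i0, ]; b <- p2[i1, ]; c <- p2[i2, ]
      if (o * area2(a, b, c) <= 1e-14 * max(1, abs(orient))) next
      others <- setdiff(idx, c(i0, i1, i2))
      inside <- FALSE
      if (length(others)) {
        for (q in others) {
          p <- p2[q, ]
          if (o * area2(a, b, p) >= 0 && o * area2(b, c, p) >= 0 &&
              o * area2(c, a, p) >= 0) { inside <- TRUE; break }
        }
      }
      if (!inside) {
        tris <- rbind(tris, c(i0, i1, i2))
        idx <- idx[idx != i1]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) {  # degenerate polygon: fall back to a fan
      for (e in 2:(length(idx) - 1L))
        tris <- rbind(tris, c(idx[1L], idx[e], idx[e + 1L]))
      return(tris)
    }
  }
  rbind(tris, matrix(idx, 1L, 3L))
}
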