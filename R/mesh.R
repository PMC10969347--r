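#' Structured triangle meshes
#'
#' A `face_mesh` is a triangle mesh with a fixed, shared topology: two meshes
#' carrying the same `topology_id` have identical vertex counts and face
#' arrays, and equal vertex indices denote the same anatomical location.
#' This vertex-wise correspondence is what the autoencoder, the defect
#' simulator and the evaluation metrics all rely on.
#'
#' @param vertices Numeric N x 3 matrix of vertex coordinates in mm.
#' @param faces Integer M x 3 matrix of 1-based vertex indices.
#' @param topology_id Character tag identifying the shared template topology.
#'
#' @return An object of class `face_mesh` with components `vertices`, `faces`
#'   and `topology_id`.
#' @export
face_mesh <- function(vertices, faces, topology_id = "anonymous") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stopf("faces must be an M x 3 matrix")
  if (nrow(vertices) < 1L || nrow(faces) < 1L)
    stopf("mesh must have positive vertex and face counts")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stopf("face indices out of range [1, %d]", nrow(vertices))
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen))
    stopf("%d degenerate triangle(s) (repeated vertex index)", sum(degen))
  structure(list(vertices = vertices, faces = faces,
                 topology_id = as.character(topology_id)),
            class = "face_mesh")
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("face_mesh: %d vertices, %d triangles (topology '%s')\n",
              nrow(x$vertices), nrow(x$faces), x$topology_id))
  invisible(x)
}

same_topology <- function(a, b) {
  identical(a$topology_id, b$topology_id) &&
    nrow(a$vertices) == nrow(b$vertices) &&
    identical(a$faces, b$faces)
}

#' Read a Wavefront OBJ triangle mesh
#'
#' Parses `v` and `f` records; texture/normal indices (`f v/vt/vn`) and all
#' other record types (`vt`, `vn`, materials, comments) are ignored.  Polygon
#' faces with more than three vertices are fan-triangulated.  OBJ 1-based
#' indexing is kept (the package indexes vertices from 1).
#'
#' @param path Path to an OBJ file.
#' @param topology_id Topology tag to attach to the mesh.
#' @return A [face_mesh()].
#' @export
read_obj <- function(path, topology_id = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stopf("OBJ parse error in %s: need at least one 'v' and one 'f' record", path)
  vert <- t(vapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"), function(tok) {
    xyz <- suppressWarnings(as.numeric(tok[1:3]))
    if (length(tok) < 3L || anyNA(xyz))
      stopf("OBJ parse error: malformed vertex record 'v %s'",
            paste(tok, collapse = " "))
    xyz
  }, numeric(3)))
  faces <- list()
  for (fl in flines) {
    tok <- strsplit(sub("^f\\s+", "", fl), "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(vapply(strsplit(tok, "/"),
                                              `[`, character(1), 1L)))
    if (length(idx) < 3L || anyNA(idx))
      stopf("OBJ parse error: malformed face record 'f %s'",
            paste(tok, collapse = " "))
    if (any(idx < 0L)) stopf("negative OBJ face indices are not supported")
    # fan triangulation for polygons
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  face_mesh(vert, do.call(rbind, faces), topology_id = topology_id)
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh A [face_mesh()].
#' @param path Output file path.
#' @param digits Decimal digits for vertex coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path, digits = 6) {
  fmt <- sprintf("v %%.%df %%.%df %%.%df", digits, digits, digits)
  vl <- sprintf(fmt, mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  fl <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(vl, fl), path)
  invisible(path)
}

#' Boundary curves
#'
#' An ordered 3D polyline, typically the rim of a surface hole (the defect
#' edge curve) or the edge of an extracted nose.
#'
#' @param points P x 3 matrix of ordered polyline coordinates in mm.
#' @param closed Logical; `TRUE` for a closed loop (last point connects back
#'   to the first).
#' @param vertex_index Optional integer vector mapping curve points to vertex
#'   indices of the mesh they came from.
#' @return An object of class `boundary_curve`.
#' @export
boundary_curve <- function(points, closed = TRUE, vertex_index = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stopf("curve points must be P x 3")
  if (closed && nrow(points) < 3L) stopf("a closed curve needs at least 3 points")
  d <- row_norms(diff(points))
  if (any(d == 0)) stopf("consecutive curve points must be distinct")
  structure(list(points = points, closed = isTRUE(closed),
                 vertex_index = vertex_index),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("boundary_curve: %d points (%s)\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Write a boundary curve as ordered XYZ text (one point per line)
#' @param curve A [boundary_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_xyz <- function(curve, path) {
  writeLines(sprintf("%.6f %.6f %.6f", curve$points[, 1], curve$points[, 2],
                     curve$points[, 3]), path)
  invisible(path)
}

# Undirected edge list (E x 2, first index < second) of a mesh.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Extract the boundary loop of a mesh
#'
#' Boundary edges are mesh edges incident to exactly one triangle.  For a
#' consistently oriented mesh, following each boundary half-edge in its
#' triangle's winding order traverses the loop in a consistent direction.
#'
#' @param mesh A [face_mesh()].
#' @param select_longest If the mesh has more than one boundary loop, return
#'   the longest (most vertices) instead of raising an error.
#' @return A closed [boundary_curve()] whose `vertex_index` gives the mesh
#'   vertex indices along the loop.
#' @export
extract_boundary <- function(mesh, select_longest = FALSE) {
  f <- mesh$faces
  half <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  n <- nrow(mesh$vertices)
  key <- (half[, 1] - 1) * n + half[, 2]
  rkey <- (half[, 2] - 1) * n + half[, 1]
  is_boundary <- !(key %in% rkey)
  be <- half[is_boundary, , drop = FALSE]
  if (nrow(be) == 0L) stopf("no boundary loop: mesh is closed")
  # chain directed boundary edges into loops
  nxt <- integer(n)
  nxt[be[, 1]] <- be[, 2]
  visited <- logical(n)
  loops <- list()
  for (s in be[, 1]) {
    if (visited[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      visited[v] <- TRUE
      v <- nxt[v]
      if (v == 0L) stopf("boundary edges do not form closed loops (non-manifold rim)")
      if (v == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  if (length(loops) > 1L && !select_longest)
    stopf("mesh has %d boundary loops; expected exactly 1 (use select_longest = TRUE to pick the longest)",
          length(loops))
  loop <- loops[[which.max(vapply(loops, length, integer(1)))]]
  boundary_curve(mesh$vertices[loop, , drop = FALSE], closed = TRUE,
                 vertex_index = loop)
}

# igraph of the mesh's vertex adjacency, edges weighted by Euclidean length.
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                   mesh$vertices[e[, 2], , drop = FALSE])
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Select the mesh region enclosed by a curve
#'
#' The curve is snapped to its nearest mesh vertices, consecutive snapped
#' vertices are joined by shortest paths along mesh edges, and the resulting
#' closed vertex path is removed from the vertex graph.  The enclosed region
#' is the union of connected components that do not contain the exterior
#' anchor vertex.
#'
#' @param mesh A [face_mesh()].
#' @param curve A closed [boundary_curve()] lying on or near the surface.
#' @param anchor Index of a vertex known to lie outside the region.  Default:
#'   the vertex farthest from the curve.
#' @return Logical vertex mask of the enclosed region (curve-path vertices are
#'   `FALSE`), with attributes `path_vertices` (the separating vertex cycle)
#'   and `anchor`.
#' @export
select_region <- function(mesh, curve, anchor = NULL) {
  if (!isTRUE(curve$closed)) stopf("select_region needs a closed curve")
  n <- nrow(mesh$vertices)
  # nearest mesh vertex for each curve point
  d2 <- outer(rowSums(curve$points^2), rep(1, n)) +
    outer(rep(1, nrow(curve$points)), rowSums(mesh$vertices^2)) -
    2 * curve$points %*% t(mesh$vertices)
  snapped <- max.col(-d2, ties.method = "first")
  snapped <- snapped[c(TRUE, diff(snapped) != 0L)]
  if (length(snapped) > 1L && snapped[1] == snapped[length(snapped)])
    snapped <- snapped[-length(snapped)]
  g <- mesh_graph(mesh)
  path <- integer(0)
  ns <- length(snapped)
  for (i in seq_len(ns)) {
    a <- snapped[i]
    b <- snapped[if (i == ns) 1L else i + 1L]
    if (a == b) next
    sp <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1]]
    path <- c(path, as.integer(sp)[-length(sp)])
  }
  path <- unique(path)
  if (length(path) < 3L) stopf("curve does not map to a separating path on the mesh")
  if (is.null(anchor)) {
    mind <- apply(d2, 2, min)  # squared distance of each vertex to the curve
    anchor <- which.max(mind)
  }
  if (anchor %in% path) stopf("anchor vertex lies on the separating path")
  keep <- setdiff(seq_len(n), path)
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  if (comp$no < 2L)
    stopf("curve does not separate the mesh into >= 2 components")
  membership <- integer(n)
  membership[keep] <- comp$membership
  mask <- membership != 0L & membership != membership[anchor]
  attr(mask, "path_vertices") <- path
  attr(mask, "anchor") <- anchor
  mask
}

#' Extract the submesh induced by a vertex mask
#'
#' Keeps faces whose three vertices are all selected and reindexes vertices.
#'
#' @param mesh A [face_mesh()].
#' @param mask Logical vertex mask (or integer vertex indices).
#' @param topology_id Topology tag for the submesh.
#' @return A [face_mesh()] with attribute `orig_index` mapping its vertices
#'   back to `mesh`.
#' @export
submesh <- function(mesh, mask, topology_id = paste0(mesh$topology_id, ":sub")) {
  if (!is.logical(mask)) {
    idx <- as.integer(mask)
    mask <- rep(FALSE, nrow(mesh$vertices))
    mask[idx] <- TRUE
  }
  keep <- which(mask)
  if (length(keep) < 3L) stopf("submesh needs at least 3 selected vertices")
  newid <- integer(nrow(mesh$vertices))
  newid[keep] <- seq_along(keep)
  fkeep <- mask[mesh$faces[, 1]] & mask[mesh$faces[, 2]] & mask[mesh$faces[, 3]]
  if (!any(fkeep)) stopf("selected vertices induce no complete triangle")
  faces <- matrix(newid[mesh$faces[fkeep, , drop = FALSE]], ncol = 3)
  out <- face_mesh(mesh$vertices[keep, , drop = FALSE], faces,
                   topology_id = topology_id)
  attr(out, "orig_index") <- keep
  out
}
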