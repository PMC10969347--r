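# Shared fixtures and independent oracles, all built in code.

# A flat triangulated g x g grid in the z = 0 plane (open disk-like sheet).
grid_sheet <- function(g = 6, spacing = 1) {
  u <- seq(0, by = spacing, length.out = g)
  verts <- cbind(rep(u, times = g), rep(u, each = g), 0)
  idx <- function(i, j) (j - 1L) * g + i
  faces <- list()
  for (j in seq_len(g - 1L)) for (i in seq_len(g - 1L)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  face_mesh(verts, do.call(rbind, faces), topology_id = sprintf("grid%d", g))
}

# A closed octahedron (no boundary).
octahedron <- function(r = 1) {
  v <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
             c(0, 0, r), c(0, 0, -r))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  face_mesh(v, f, topology_id = "octahedron")
}

# A fan disk: K rim vertices around a center vertex (single boundary loop).
disk_fan <- function(K = 8, r = 1) {
  ang <- 2 * pi * (seq_len(K) - 1) / K
  v <- rbind(c(0, 0, 0), cbind(r * cos(ang), r * sin(ang), 0))
  f <- cbind(1, 1 + seq_len(K), 1 + c(seq_len(K)[-1], 1L))
  face_mesh(v, f, topology_id = sprintf("disk%d", K))
}

# Random well-formed mesh for oracle comparisons: jittered grid sheet.
random_mesh <- function(g = 8, seed = 1, jitter = 0.3) {
  m <- grid_sheet(g)
  set.seed(seed)
  m$vertices <- m$vertices + matrix(rnorm(length(m$vertices), sd = jitter),
                                    ncol = 3)
  m$topology_id <- sprintf("random-g%d-s%d", g, seed)
  m
}

# --- independent oracles ----------------------------------------------------

# Brute-force unidirectional chamfer: explicit double loop.
chamfer_bruteforce <- function(s1, s2) {
  d2min <- numeric(nrow(s1))
  for (i in seq_len(nrow(s1))) {
    best <- Inf
    for (j in seq_len(nrow(s2))) {
      d2 <- sum((s1[i, ] - s2[j, ])^2)
      if (d2 < best) best <- d2
    }
    d2min[i] <- best
  }
  mean(d2min)
}

# Independent point-to-triangle closest distance: project onto the plane,
# use the barycentric test, else clamp onto each edge segment.
point_triangle_dist_oracle <- function(p, a, b, c3) {
  n <- cross3(b - a, c3 - a)
  nn <- sum(n * n)
  seg_d2 <- function(p, q0, q1) {
    d <- q1 - q0
    t_ <- sum((p - q0) * d) / sum(d * d)
    t_ <- min(max(t_, 0), 1)
    sum((p - (q0 + t_ * d))^2)
  }
  if (nn > 0) {
    t_ <- sum((p - a) * n) / nn
    proj <- p - t_ * n
    # barycentric coordinates of proj
    v0 <- b - a; v1 <- c3 - a; v2 <- proj - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    vb <- (d11 * d20 - d01 * d21) / den
    wb <- (d00 * d21 - d01 * d20) / den
    if (vb >= 0 && wb >= 0 && vb + wb <= 1) return(sqrt(sum((p - proj)^2)))
  }
  sqrt(min(seg_d2(p, a, b), seg_d2(p, b, c3), seg_d2(p, a, c3)))
}

# Min distance of each point to any triangle of mesh, by exhaustive loop.
mesh_dist_oracle <- function(points, mesh) {
  f <- mesh$faces
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    min(vapply(seq_len(nrow(f)), function(k) {
      point_triangle_dist_oracle(p, mesh$vertices[f[k, 1], ],
                                 mesh$vertices[f[k, 2], ],
                                 mesh$vertices[f[k, 3], ])
    }, numeric(1)))
  }, numeric(1))
}

# Count boundary edges (triangle-incidence exactly 1) by brute force.
count_boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) == 1L)
}

# Small benchmark template shared by several test files (cheap, cached).
tiny_template <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_template(24)
    val
  }
})
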