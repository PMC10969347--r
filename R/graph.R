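#' Multi-level face graph for graph convolutions
#'
#' Builds the propagation operators and pooling hierarchy consumed by the
#' autoencoder.  Level 0 is the template mesh graph; each coarser level is
#' produced by vertex clustering via greedy edge contraction ordered by
#' quadric error (the standard mesh-simplification cost), so coarse vertices
#' cover geometrically coherent patches.  Propagation operators are
#' first-order neighborhood averages with self-loops: `P = D^-1 (A + I)`,
#' built from the symmetric adjacency; rows sum to 1, so a constant signal
#' is preserved exactly.
#'
#' @param mesh A [face_mesh()] (the template; must be connected, no isolated
#'   vertices).
#' @param n_levels Number of pooling levels (>= 1).
#' @param ratio Target coarsening ratio per level (default 4).
#' @return An object of class `face_graph`: `adj` (list of `n_levels + 1`
#'   sparse row-stochastic operators), `pools` (list of averaging pool
#'   matrices, coarse x fine), `unpools` (smoothed copy-up operators, rows
#'   convex combinations), `sizes` (vertex count per level), `topology_id`.
#' @export
build_face_graph <- function(mesh, n_levels = 3, ratio = 4) {
  if (n_levels < 1L) stopf("n_levels must be >= 1")
  n <- nrow(mesh$vertices)
  edges <- mesh_edges(mesh)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (any(deg == 0L)) stopf("mesh has %d isolated vertex/vertices", sum(deg == 0L))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::components(g)$no != 1L) stopf("mesh must be connected")
  adj <- list(normalized_adjacency(edges, n))
  pools <- list()
  unpools <- list()
  sizes <- n
  pos <- mesh$vertices
  quad <- vertex_quadrics(mesh)
  cur_edges <- edges
  cur_n <- n
  for (lev in seq_len(n_levels)) {
    target <- ceiling(cur_n / ratio)
    if (target < 4L && target < cur_n)
      stopf("coarsening to level %d would produce < 4 vertices", lev)
    total_map <- seq_len(cur_n)
    repeat {
      nclust_now <- max(total_map)
      if (nclust_now <= target) break
      res <- contract_pass(cur_edges, seq_len(nclust_now), nclust_now,
                           pos, quad, max_merges = nclust_now - target)
      if (res$nclust == nclust_now) break
      total_map <- res$cl[total_map]
      tmp <- cluster_collapse(cur_edges, res$cl, res$nclust, pos, quad)
      cur_edges <- tmp$edges
      pos <- tmp$pos
      quad <- tmp$quad
    }
    nclust <- max(total_map)
    counts <- tabulate(total_map, nbins = nclust)
    P <- Matrix::sparseMatrix(i = total_map, j = seq_len(cur_n),
                              x = 1 / counts[total_map],
                              dims = c(nclust, cur_n))
    U <- Matrix::sparseMatrix(i = seq_len(cur_n), j = total_map, x = 1,
                              dims = c(cur_n, nclust))
    # smooth the copy-up so decoded fields vary within clusters rather than
    # staying piecewise constant (rows remain convex combinations)
    U <- adj[[lev]] %*% (adj[[lev]] %*% U)
    pools[[lev]] <- P
    unpools[[lev]] <- U
    sizes <- c(sizes, nclust)
    adj[[lev + 1L]] <- normalized_adjacency(cur_edges, nclust)
    cur_n <- nclust
  }
  structure(list(adj = adj, pools = pools, unpools = unpools,
                 sizes = sizes, n_levels = n_levels,
                 topology_id = mesh$topology_id),
            class = "face_graph")
}

#' @export
print.face_graph <- function(x, ...) {
  cat(sprintf("face_graph: %d pooling level(s), vertex counts %s\n",
              x$n_levels, paste(x$sizes, collapse = " -> ")))
  invisible(x)
}

# Row-stochastic propagation operator D^-1 (A + I) from an edge list.
normalized_adjacency <- function(edges, n) {
  i <- c(edges[, 1], edges[, 2], seq_len(n))
  j <- c(edges[, 2], edges[, 1], seq_len(n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A@x <- pmin(A@x, 1)  # collapse duplicate edges
  d <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / d) %*% A
}

# Per-vertex 4x4 error quadrics summed from incident face planes,
# stored as n x 10 (upper triangle of symmetric Q).
vertex_quadrics <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (c3[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c3[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c3[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c3[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1]))
  len <- row_norms(nrm)
  len[len == 0] <- 1
  nrm <- nrm / len
  d <- -rowSums(nrm * a)
  # plane quadric entries (upper triangle of [n d][n d]^T)
  pq <- cbind(nrm[, 1]^2, nrm[, 1] * nrm[, 2], nrm[, 1] * nrm[, 3], nrm[, 1] * d,
              nrm[, 2]^2, nrm[, 2] * nrm[, 3], nrm[, 2] * d,
              nrm[, 3]^2, nrm[, 3] * d,
              d^2)
  q <- matrix(0, nrow(v), 10)
  for (col in 1:3) {
    idx <- f[, col]
    for (k in 1:10) {
      q[, k] <- q[, k] + unname(tapply_sum(pq[, k], idx, nrow(v)))
    }
  }
  q
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Quadric error of placing point p (rows) under quadric q (rows, 10-vector).
quadric_cost <- function(q, p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  q[, 1] * x * x + 2 * q[, 2] * x * y + 2 * q[, 3] * x * z + 2 * q[, 4] * x +
    q[, 5] * y * y + 2 * q[, 6] * y * z + 2 * q[, 7] * y +
    q[, 8] * z * z + 2 * q[, 9] * z +
    q[, 10]
}

# One greedy pairing pass: contract cheapest edges (quadric error at the
# midpoint) until max_merges merges are done or no independent edge remains.
contract_pass <- function(edges, cl, nclust, pos, quad, max_merges) {
  mid <- (pos[edges[, 1], , drop = FALSE] + pos[edges[, 2], , drop = FALSE]) / 2
  cost <- quadric_cost(quad[edges[, 1], , drop = FALSE] +
                         quad[edges[, 2], , drop = FALSE], mid)
  ord <- order(cost, edges[, 1], edges[, 2])
  merged <- logical(nclust)
  partner <- integer(nclust)
  merges <- 0L
  for (k in ord) {
    if (merges >= max_merges) break
    u <- edges[k, 1]; v <- edges[k, 2]
    if (merged[u] || merged[v]) next
    merged[u] <- merged[v] <- TRUE
    partner[u] <- v; partner[v] <- u
    merges <- merges + 1L
  }
  if (merges == 0L) return(list(cl = seq_len(nclust), nclust = nclust))
  newcl <- integer(nclust)
  nxt <- 0L
  for (u in seq_len(nclust)) {
    if (newcl[u] != 0L) next
    nxt <- nxt + 1L
    newcl[u] <- nxt
    if (merged[u] && newcl[partner[u]] == 0L) newcl[partner[u]] <- nxt
  }
  list(cl = newcl, nclust = nxt)
}

# Collapse edges/positions/quadrics onto cluster representatives.
cluster_collapse <- function(edges, cl, nclust, pos, quad) {
  e2 <- cbind(cl[edges[, 1]], cl[edges[, 2]])
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  e2 <- unique(cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2])))
  counts <- tabulate(cl, nbins = nclust)
  newpos <- rowsum(pos, cl) / counts
  newquad <- rowsum(quad, cl)
  list(edges = e2, pos = newpos, quad = newquad)
}
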