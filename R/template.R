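#' Nasal subunit labels
#'
#' The nine anatomical subunits of the external nose used to localize the
#' maximum surface deviation, plus the `non_nasal` background label.
#' @export
NASAL_SUBUNITS <- c("nasal_dorsum", "nasal_sidewall_L", "nasal_sidewall_R",
                    "nasal_tip", "nasal_columella",
                    "soft_triangle_L", "soft_triangle_R",
                    "nasal_ala_L", "nasal_ala_R")

#' Build the synthetic structured face template
#'
#' Deterministic analytic stand-in for an average-face template: a smooth
#' facial dome with a protruding nose modelled as a sum of anisotropic
#' Gaussian bumps (dorsal ridge, tip, alae), triangulated as a regular
#' `g x g` grid and closed at the back by a single apex vertex so the only
#' boundary loop a simulated defect creates is the defect rim itself.  The
#' construction is bilaterally symmetric about the mid-sagittal plane
#' (`x = 0`).  Units are mm: the face sheet spans 120 mm (width) by 160 mm
#' (height) with nasal relief of roughly 10-18 mm.
#'
#' Per-vertex region labels partition the nose into the nine classical
#' subunits (dorsum, paired sidewalls, tip, columella, paired soft
#' triangles, paired alae) by parametric zones of the bump construction;
#' everything else is `non_nasal`.
#'
#' @param grid_resolution Grid side `g` (>= 16); the template has `g^2 + 1`
#'   vertices.
#' @return An object of class `face_template`: `mesh` (a [face_mesh()]),
#'   `region_labels` (factor, one of the nine subunits or `non_nasal`),
#'   `nose_mask` (logical), `grid_resolution`.
#' @export
make_template <- function(grid_resolution = 40) {
  g <- as.integer(grid_resolution)
  if (g < 16L) stopf("grid_resolution must be >= 16")
  u <- seq(-60, 60, length.out = g)    # width, mm (x)
  v <- seq(-80, 80, length.out = g)    # height, mm (y); nose around v in [-24, 20]
  uu <- rep(u, times = g)
  vv <- rep(v, each = g)

  # facial dome plus nasal relief (all even in u => bilateral symmetry)
  dome <- 35 * exp(-((uu / 55)^2 + (vv / 75)^2))
  ridge_profile <- exp(-((vv - 8) / 16)^2)          # dorsum, high near root
  ridge <- 9 * exp(-(uu / 6)^2) * ridge_profile
  tip <- 8 * exp(-((uu / 6.5)^2 + ((vv + 8) / 6)^2))
  alae <- 5 * exp(-(((abs(uu) - 10.5) / 4.5)^2 + ((vv + 12) / 5.5)^2))
  zz <- dome + ridge + tip + alae

  verts <- cbind(uu, vv, zz)
  # back apex closing the outer rim
  apex <- c(0, 0, -40)
  verts <- rbind(verts, apex)
  nv <- g * g + 1L

  idx <- function(i, j) (j - 1L) * g + i  # i: column (u), j: row (v)
  faces <- vector("list", 2L * (g - 1L)^2 + 4L * (g - 1L))
  k <- 0L
  for (j in seq_len(g - 1L)) {
    for (i in seq_len(g - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c2 <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      k <- k + 1L; faces[[k]] <- c(a, b, c2)
      k <- k + 1L; faces[[k]] <- c(a, c2, d)
    }
  }
  # rim fan to the apex (consistent winding around the rim)
  rim <- c(idx(seq_len(g), 1L),                 # bottom row, left -> right
           idx(g, 1L + seq_len(g - 1L)),        # right column, up
           idx(g - seq_len(g - 1L), g),         # top row, right -> left
           idx(1L, g - seq_len(g - 2L)))        # left column, down (to row 2)
  nr <- length(rim)
  ap <- nv
  for (r in seq_len(nr)) {
    k <- k + 1L
    faces[[k]] <- c(rim[r], ap, rim[if (r == nr) 1L else r + 1L])
  }
  mesh <- face_mesh(verts, do.call(rbind, faces), topology_id =
                      sprintf("synthetic-face-g%d", g))

  labels <- rep("non_nasal", nv)
  # nose extent: v in [-24, 20], half-width w(v) piecewise-linear
  knots_v <- c(-24, -18, -10, 0, 10, 20)
  knots_w <- c(6, 15, 16, 11, 9, 8)
  in_band <- vv >= -24 & vv <= 20
  w <- stats::approx(knots_v, knots_w, xout = pmin(pmax(vv, -24), 20))$y
  nose <- in_band & abs(uu) <= w
  au <- abs(uu)
  upper <- nose & vv >= -4
  mid <- nose & vv < -4 & vv >= -14
  lower <- nose & vv < -14
  lab_grid <- labels[seq_len(g * g)]
  lab_grid[upper & au <= 4.5] <- "nasal_dorsum"
  lab_grid[upper & au > 4.5 & uu < 0] <- "nasal_sidewall_L"
  lab_grid[upper & au > 4.5 & uu > 0] <- "nasal_sidewall_R"
  lab_grid[mid & au <= 5] <- "nasal_tip"
  lab_grid[mid & au > 5 & au <= 9 & uu < 0] <- "soft_triangle_L"
  lab_grid[mid & au > 5 & au <= 9 & uu > 0] <- "soft_triangle_R"
  lab_grid[mid & au > 9 & uu < 0] <- "nasal_ala_L"
  lab_grid[mid & au > 9 & uu > 0] <- "nasal_ala_R"
  lab_grid[lower & au <= 4] <- "nasal_columella"
  lab_grid[lower & au > 4 & uu < 0] <- "nasal_ala_L"
  lab_grid[lower & au > 4 & uu > 0] <- "nasal_ala_R"
  labels[seq_len(g * g)] <- lab_grid
  labels <- factor(labels, levels = c(NASAL_SUBUNITS, "non_nasal"))
  structure(list(mesh = mesh,
                 region_labels = labels,
                 nose_mask = labels != "non_nasal",
                 grid_resolution = g),
            class = "face_template")
}

#' @export
print.face_template <- function(x, ...) {
  cat(sprintf("face_template: grid %d (%d vertices), %d nose vertices in %d subunits\n",
              x$grid_resolution, nrow(x$mesh$vertices), sum(x$nose_mask),
              length(setdiff(unique(as.character(x$region_labels[x$nose_mask])), "non_nasal"))))
  invisible(x)
}

#' Low-rank smooth population model of inter-individual shape variation
#'
#' Stands in for the shape variability of a clinical scan population: `K`
#' spatially smooth per-vertex displacement fields (seeded Gaussian fields
#' smoothed by repeated neighborhood averaging on the template graph and
#' normalized to unit per-vertex RMS), each with a standard deviation in mm.
#' Sampled faces are the template plus a random linear combination of the
#' fields, so inter-individual variation is globally correlated: the shape
#' of the nose co-varies with the rest of the face, which is the property
#' defect-guided latent fitting exploits.
#'
#' @param template A [make_template()] result.
#' @param K Number of basis fields (default 8).
#' @param scales Standard deviations in mm, positive and non-increasing
#'   (default 3.0 down to 0.5 mm).
#' @param smooth_iters Neighborhood-averaging passes applied to each raw
#'   Gaussian field (default 40; more = smoother).
#' @param seed Integer seed for the basis fields.
#' @param max_scale_fraction Guard: error if any scale exceeds this fraction
#'   of the template bounding-box diagonal (default 0.05).
#' @return An object of class `population_model`: `basis` (list of K N x 3
#'   fields), `scales`, `seed`, `smoothness` (max per-edge displacement
#'   difference over all fields).
#' @export
population_model <- function(template, K = 8,
                             scales = seq(3.0, 0.5, length.out = K),
                             smooth_iters = 40, seed = 1,
                             max_scale_fraction = 0.05) {
  mesh <- template$mesh
  if (length(scales) != K) stopf("need exactly K scales")
  if (any(scales < 0)) stopf("scales must be non-negative")
  if (any(diff(scales) > 1e-12)) stopf("scales must be non-increasing")
  bbox <- apply(mesh$vertices, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  if (any(scales > max_scale_fraction * diag_len))
    stopf("scale %.2f mm exceeds %.0f%% of the template bounding-box diagonal (%.1f mm)",
          max(scales), 100 * max_scale_fraction, diag_len)
  n <- nrow(mesh$vertices)
  P <- normalized_adjacency(mesh_edges(mesh), n)
  basis <- with_local_seed(seed, {
    lapply(seq_len(K), function(k) {
      b <- matrix(stats::rnorm(n * 3), n, 3)
      for (it in seq_len(smooth_iters)) b <- as.matrix(P %*% b)
      b / sqrt(mean(rowSums(b * b)))
    })
  })
  e <- mesh_edges(mesh)
  smoothness <- max(vapply(basis, function(b)
    max(row_norms(b[e[, 1], , drop = FALSE] - b[e[, 2], , drop = FALSE])),
    numeric(1)))
  structure(list(basis = basis, scales = as.numeric(scales), K = K,
                 seed = seed, smoothness = smoothness,
                 topology_id = mesh$topology_id),
            class = "population_model")
}

#' Sample a population of corresponded synthetic faces
#'
#' Each face is `template + sum_k c_k * basis_k` with independent
#' `c_k ~ Normal(0, scales_k^2)`.  All outputs share the template topology.
#'
#' @param template A [make_template()] result.
#' @param model A [population_model()].
#' @param n Number of faces.
#' @param seed Integer seed for the coefficients.
#' @return List of `n` [face_mesh()] objects; the coefficient matrix is
#'   attached as attribute `coefficients` (n x K).
#' @export
sample_population <- function(template, model, n, seed = 1) {
  if (n < 1L) stopf("n must be >= 1")
  if (!identical(model$topology_id, template$mesh$topology_id))
    stopf("population model was built for a different template topology")
  coef <- with_local_seed(seed, {
    matrix(stats::rnorm(n * model$K), n, model$K) %*% diag(model$scales, model$K)
  })
  base <- template$mesh$vertices
  out <- lapply(seq_len(n), function(i) {
    disp <- Reduce(`+`, Map(function(c_k, b) c_k * b, coef[i, ], model$basis))
    face_mesh(base + disp, template$mesh$faces,
              topology_id = template$mesh$topology_id)
  })
  attr(out, "coefficients") <- coef
  out
}

#' Simulate a full nasal defect
#'
#' Deletes the template's nose region (above the nasal root, bilaterally
#' inside the inner canthi, below the columella in the parametric template)
#' from a face: nose vertices and all incident triangles are removed.  The
#' deleted nasal submesh is returned as the ground-truth `nose_original`,
#' and the rim of the hole as the defect edge curve.
#'
#' @param face A [face_mesh()] sharing the template topology.
#' @param template The [make_template()] defining the nose region.
#' @param source_id Identifier of the intact source face.
#' @return An object of class `defective_face`: `mesh` (the defective face),
#'   `defect_curve` (closed [boundary_curve()]), `nose_original`
#'   (a [face_mesh()] with attributes `orig_index` and `region_labels`),
#'   `source_id`.
#' @export
simulate_defect <- function(face, template, source_id = "unknown") {
  if (!same_topology(face, template$mesh))
    stopf("face does not share the template topology ('%s' vs '%s')",
          face$topology_id, template$mesh$topology_id)
  keep <- !template$nose_mask
  defect <- submesh(face, keep, topology_id =
                      paste0(face$topology_id, ":defect"))
  nose <- submesh(face, template$nose_mask, topology_id =
                    paste0(face$topology_id, ":nose"))
  attr(nose, "region_labels") <-
    as.character(template$region_labels[attr(nose, "orig_index")])
  curve <- extract_boundary(defect)
  structure(list(mesh = defect, defect_curve = curve, nose_original = nose,
                 source_id = source_id),
            class = "defective_face")
}

#' @export
print.defective_face <- function(x, ...) {
  cat(sprintf("defective_face (source '%s'): %d vertices, defect rim of %d points\n",
              x$source_id, nrow(x$mesh$vertices), nrow(x$defect_curve$points)))
  invisible(x)
}

#' Apply a random rigid transform (test harness for rigid recovery)
#'
#' Draws a rotation with angle uniform in `[0, max_angle_deg]` about a
#' uniformly random axis and a translation with norm uniform in
#' `[0, max_translation]`, applies them as `R v + T`, and returns the
#' ground-truth transform.
#'
#' @param mesh A [face_mesh()].
#' @param seed Integer seed.
#' @param max_angle_deg Maximum rotation angle in degrees (default 30).
#' @param max_translation Maximum translation norm in mm (default 20).
#' @return List with `mesh` (transformed) and `transform` (a
#'   [rigid_transform()]).
#' @export
apply_random_rigid <- function(mesh, seed = 1, max_angle_deg = 30,
                               max_translation = 20) {
  tr <- with_local_seed(seed, {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    angle <- stats::runif(1, 0, max_angle_deg * pi / 180)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    shift <- stats::runif(1, 0, max_translation)
    rigid_transform(axis_angle = axis * angle, translation = dir * shift)
  })
  out <- mesh
  out$vertices <- apply_rigid(mesh$vertices, tr)
  list(mesh = out, transform = tr)
}
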