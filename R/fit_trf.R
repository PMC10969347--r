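# Defect-guided construction of the personalized 3D target reference face:
# joint minimization of the unidirectional chamfer distance over the latent
# code and a rigid transform of the generated face.

#' Fitting configuration for [fit_trf()]
#'
#' The objective is `CD(S1, R * decode(z) + T) + lambda_reg * (||z|| - 1)^2`
#' with nearest-neighbor correspondences recomputed every iteration.  Adam
#' updates use per-block learning rates (latent coordinates are O(1),
#' axis-angle radians and translations in mm live on different scales) with
#' cosine decay to a small floor so late iterations refine rather than
#' oscillate.
#'
#' @param max_iters Maximum iterations per restart (default 400).
#' @param lr_z,lr_rot,lr_trans Initial Adam learning rates for the latent
#'   code, the axis-angle rotation (radians) and the translation (mm);
#'   defaults 0.02, 0.02, 1.0.
#' @param lr_floor Fraction of the initial rate the cosine decay ends at
#'   (default 1e-3).
#' @param lambda_reg Spherical regularization weight, reusing the training
#'   weight by default (0.01).
#' @param convergence_tol Relative objective change defining convergence
#'   (default 1e-6, checked over a 10-iteration window).
#' @param restarts Number of restarts (default 3).  The first restart uses
#'   the supplied (or default) initialization; later restarts draw a fresh
#'   latent vector on the unit sphere and a random initial rotation of up to
#'   `restart_rot_deg` degrees, and the best final objective wins.
#' @param restart_rot_deg Maximum initial-rotation perturbation for restarts
#'   beyond the first, in degrees (default 30).
#' @param optimize Character subset of `c("z", "rotation", "translation")`;
#'   blocks not listed stay frozen at their initial values.
#' @param rigid_update `"gradient"` (default): the rotation and translation
#'   follow Adam steps on the axis-angle parameterization, jointly with the
#'   latent code.  `"icp"`: they are instead re-solved in closed form
#'   (Kabsch) from the current nearest-neighbor correspondences each
#'   iteration, alternating with the latent gradient step; this converges
#'   much faster and to machine precision when an exact rigid match exists.
#' @param coarse_fraction Fraction of the iterations during which
#'   correspondences are searched against a denser surface sampling of the
#'   generated face (vertices plus edge midpoints and face centroids) rather
#'   than its vertices alone (default 0.5).  The vertex lattice by itself
#'   creates spurious chamfer minima at one-cell misalignments; the denser
#'   sampling smooths them away during coarse alignment.  The reported
#'   objective is always the vertex-set chamfer distance.
#' @param z_init_seed Seed for the random initializations.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_iters = 400, lr_z = 0.02, lr_rot = 0.02,
                       lr_trans = 1.0, lr_floor = 1e-3, lambda_reg = 0.01,
                       convergence_tol = 1e-6, restarts = 3,
                       restart_rot_deg = 30,
                       optimize = c("z", "rotation", "translation"),
                       rigid_update = c("gradient", "icp"),
                       coarse_fraction = 0.5,
                       z_init_seed = 1) {
  rigid_update <- match.arg(rigid_update)
  if (coarse_fraction < 0 || coarse_fraction > 1)
    stopf("coarse_fraction must be in [0, 1]")
  if (max_iters < 1) stopf("max_iters must be >= 1")
  if (convergence_tol <= 0) stopf("convergence_tol must be > 0")
  bad <- setdiff(optimize, c("z", "rotation", "translation"))
  if (length(bad)) stopf("unknown optimize block(s): %s", paste(bad, collapse = ", "))
  structure(list(max_iters = max_iters, lr_z = lr_z, lr_rot = lr_rot,
                 lr_trans = lr_trans, lr_floor = lr_floor,
                 lambda_reg = lambda_reg, convergence_tol = convergence_tol,
                 restarts = restarts, restart_rot_deg = restart_rot_deg,
                 optimize = optimize, rigid_update = rigid_update,
                 coarse_fraction = coarse_fraction,
                 z_init_seed = z_init_seed),
            class = "fit_config")
}

#' Fit a personalized 3D target reference face to a defective face
#'
#' Gradient-based joint minimization of the unidirectional chamfer distance
#' from the defective face's vertices to the rigidly transformed decoded
#' face, plus spherical latent regularization, over the latent code `z`,
#' an axis-angle rotation and a translation.  The decoder acts purely as a
#' generator (the encoder plays no role).  The best restart by final
#' objective is returned.
#'
#' @param defect A `defective_face` (from [simulate_defect()]), a
#'   [face_mesh()], or a bare point matrix: its vertices form `S1`.
#' @param model A fitted [train_face_autoencoder()] model.
#' @param config A [fit_config()].
#' @param z_init Optional initial latent vector (used for the first restart;
#'   further restarts draw random unit-sphere vectors).
#' @param transform_init Optional initial [rigid_transform()]; by default
#'   the rotation starts at identity and the translation matches the
#'   centroid of `S1` to the centroid of the decoded face's non-nasal
#'   region (or the whole decoded face when no template is available).
#' @param template Optional [make_template()]; when supplied, the centroid
#'   initialization uses only non-nose vertices of the decoded face, which
#'   matches the anatomy actually present in a full nasal defect.
#' @param verbose Print objective every 50 iterations.
#' @return An object of class `trf_fit`: `z_star`, `transform_star`
#'   (a [rigid_transform()]), `trf` (the decoded, transformed face mesh),
#'   `objective_history` (vector; entry 1 is the initial objective),
#'   `converged`, `restart`, `final_objective`.
#' @export
fit_trf <- function(defect, model, config = fit_config(), z_init = NULL,
                    transform_init = NULL, template = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "face_autoencoder"))
  S1 <- if (inherits(defect, "defective_face")) defect$mesh$vertices
        else if (inherits(defect, "face_mesh")) defect$vertices
        else as.matrix(defect)
  if (nrow(S1) == 0L) stopf("defective face is empty")
  params <- model$params
  graph <- model$graph
  D <- params$meta$D
  ops <- batch_ops(graph, 1L)
  nose_mask <- if (!is.null(template)) template$nose_mask else NULL

  runs <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    opt_z <- "z" %in% config$optimize
    z0 <- if (!is.null(z_init) && (r == 1L || !opt_z)) as.numeric(z_init) else
      with_local_seed(derive_seed(config$z_init_seed, r), {
        v <- stats::rnorm(D); v / sqrt(sum(v^2))
      })
    if (length(z0) != D) stopf("z_init has length %d; model D = %d", length(z0), D)
    w_init <- if (r == 1L) NULL else
      with_local_seed(derive_seed(config$z_init_seed, 1000 + r), {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ax * stats::runif(1, 0, config$restart_rot_deg * pi / 180)
      })
    run <- tryCatch(
      fit_trf_once(S1, params, graph, ops, config, z0, transform_init,
                   nose_mask, verbose, w_init = w_init),
      error = function(e) e)
    runs[[r]] <- run
    if (verbose && !inherits(run, "error"))
      message(sprintf("restart %d: objective %.6f", r, run$final_objective))
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  if (!any(ok))
    stopf("all %d restart(s) failed; first error: %s", config$restarts,
          conditionMessage(runs[[1]]))
  objs <- vapply(runs[ok], `[[`, numeric(1), "final_objective")
  best <- which(ok)[which.min(objs)]
  out <- runs[[best]]
  out$restart <- best
  out
}

fit_trf_once <- function(S1, params, graph, ops, config, z0, transform_init,
                         nose_mask, verbose, w_init = NULL) {
  dec0 <- fmgen_decode_fwd(params, ops, matrix(z0, 1))
  S2_0 <- denormalize_stack(params, dec0$out_n, 1L)
  if (!is.null(transform_init)) {
    w <- transform_init$axis_angle
    tv <- transform_init$translation
  } else {
    w <- w_init %||% c(0, 0, 0)
    R0 <- rotation_from_axis_angle(w)
    ref <- if (!is.null(nose_mask)) S2_0[!nose_mask, , drop = FALSE] else S2_0
    tv <- colMeans(S1) - colMeans(ref %*% t(R0))
  }
  z <- z0
  opt_z <- "z" %in% config$optimize
  opt_r <- "rotation" %in% config$optimize
  opt_t <- "translation" %in% config$optimize

  # per-block Adam state
  mstate <- list(z = 0 * z, w = numeric(3), t = numeric(3))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- numeric(0)
  n1 <- nrow(S1)
  dec <- dec0
  S2 <- S2_0
  converged <- FALSE
  best <- list(obj = Inf)

  # Denser surface sampling (vertices + edge midpoints + face centroids) for
  # the coarse iterations: correspondences against the vertex lattice alone
  # have spurious minima at one-cell misalignments; the extra samples smooth
  # them out.  The recorded objective is always the vertex-set chamfer.
  Gaug <- NULL
  n_coarse <- 0L
  if (config$coarse_fraction > 0 && (opt_r || opt_t || opt_z)) {
    Gaug <- surface_sampling_matrix(params$template_faces, nrow(S2_0))
    n_coarse <- as.integer(floor(config$coarse_fraction * config$max_iters))
  }

  for (it in seq_len(config$max_iters + 1L)) {
    R <- rotation_from_axis_angle(w)
    Y <- S2 %*% t(R) + matrix(tv, nrow(S2), 3, byrow = TRUE)
    nn <- nearest_neighbor(S1, Y)
    cd <- mean(nn$dist2)
    znorm <- sqrt(sum(z * z))
    obj <- cd + config$lambda_reg * (znorm - 1)^2
    if (!is.finite(obj)) stopf("non-finite objective at iteration %d", it - 1L)
    hist <- c(hist, obj)
    if (obj < best$obj)
      best <- list(obj = obj, z = z, w = w, tv = tv, it = it - 1L)
    if (verbose && (it - 1L) %% 50 == 0)
      message(sprintf("  iter %4d  objective %.6f", it - 1L, obj))
    if (it > config$max_iters) break
    if (it > 10L) {
      prev <- hist[it - 10L]
      if (abs(prev - obj) <= config$convergence_tol * max(abs(prev), 1e-12)) {
        converged <- TRUE
        break
      }
    }

    coarse <- it <= n_coarse
    if (coarse) {
      Smatch <- as.matrix(Gaug %*% S2)
      Ymatch <- Smatch %*% t(R) + matrix(tv, nrow(Smatch), 3, byrow = TRUE)
      nn_u <- nearest_neighbor(S1, Ymatch)
    } else {
      Smatch <- S2
      Ymatch <- Y
      nn_u <- nn
    }

    # gradient of the matched error w.r.t. transformed points, scattered
    dY <- matrix(0, nrow(Ymatch), 3)
    resid <- 2 / n1 * (Ymatch[nn_u$index, , drop = FALSE] - S1)
    for (c3 in 1:3)
      dY[, c3] <- unname(tapply_sum(resid[, c3], nn_u$index, nrow(Ymatch)))

    lr_scale <- config$lr_floor + (1 - config$lr_floor) *
      0.5 * (1 + cos(pi * (it - 1) / config$max_iters))

    if (config$rigid_update == "icp" && (opt_r || opt_t)) {
      # closed-form rigid update (Kabsch) on the current correspondences
      P <- Smatch[nn_u$index, , drop = FALSE]
      pbar <- colMeans(P)
      qbar <- colMeans(S1)
      Hm <- t(P - matrix(pbar, n1, 3, byrow = TRUE)) %*%
        (S1 - matrix(qbar, n1, 3, byrow = TRUE))
      sv <- svd(Hm)
      Rn <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
      if (opt_r) {
        w <- axis_angle_from_rotation(Rn)
        if (opt_t) tv <- qbar - as.numeric(Rn %*% pbar)
      } else {
        tv <- qbar - as.numeric(rotation_from_axis_angle(w) %*% pbar)
      }
    }
    if (config$rigid_update == "gradient" && opt_t) {
      gt <- colSums(dY)
      mstate$t <- b1 * mstate$t + (1 - b1) * gt
      vstate$t <- b2 * vstate$t + (1 - b2) * gt^2
      tv <- tv - config$lr_trans * lr_scale *
        (mstate$t / (1 - b1^it)) / (sqrt(vstate$t / (1 - b2^it)) + eps)
    }
    if (config$rigid_update == "gradient" && opt_r) {
      dR <- t(dY) %*% Smatch
      J <- rotation_jacobian(w)
      gw <- vapply(J, function(Jk) sum(dR * Jk), numeric(1))
      mstate$w <- b1 * mstate$w + (1 - b1) * gw
      vstate$w <- b2 * vstate$w + (1 - b2) * gw^2
      w <- w - config$lr_rot * lr_scale *
        (mstate$w / (1 - b1^it)) / (sqrt(vstate$w / (1 - b2^it)) + eps)
    }
    if (opt_z) {
      dSmatch <- dY %*% R
      dS2 <- if (coarse) as.matrix(Matrix::crossprod(Gaug, dSmatch)) else dSmatch
      dout_n <- dS2 * params$norm$scale
      dz <- as.numeric(fmgen_decode_bwd(params, ops, dec$cache, dout_n,
                                        param_grads = FALSE)$dz)
      if (znorm > 1e-12)
        dz <- dz + config$lambda_reg * 2 * (znorm - 1) * z / znorm
      mstate$z <- b1 * mstate$z + (1 - b1) * dz
      vstate$z <- b2 * vstate$z + (1 - b2) * dz^2
      z <- z - config$lr_z * lr_scale *
        (mstate$z / (1 - b1^it)) / (sqrt(vstate$z / (1 - b2^it)) + eps)
      dec <- fmgen_decode_fwd(params, ops, matrix(z, 1))
      S2 <- denormalize_stack(params, dec$out_n, 1L)
    }
  }

  # report the best iterate seen
  z <- best$z; w <- best$w; tv <- best$tv
  tr <- rigid_transform(axis_angle = w, translation = tv)
  dec_best <- fmgen_decode_fwd(params, ops, matrix(z, 1))
  S2_best <- denormalize_stack(params, dec_best$out_n, 1L)
  trf <- face_mesh(apply_rigid(S2_best, tr), params$template_faces,
                   topology_id = params$meta$topology_id)
  structure(list(z_star = z, transform_star = tr, trf = trf,
                 objective_history = hist, converged = converged,
                 final_objective = best$obj, best_iter = best$it),
            class = "trf_fit")
}

#' @export
print.trf_fit <- function(x, ...) {
  cat(sprintf("trf_fit: objective %.6f mm^2 after %d iteration(s)%s (restart %s)\n",
              x$final_objective, length(x$objective_history) - 1L,
              if (x$converged) ", converged" else "",
              x$restart %||% 1L))
  print(x$transform_star)
  invisible(x)
}


# Sparse map from mesh vertices to a denser surface sampling: the vertices
# themselves, edge midpoints, and face centroids.
surface_sampling_matrix <- function(faces, n) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  ne <- nrow(e)
  nf <- nrow(faces)
  i <- c(seq_len(n),
         rep(n + seq_len(ne), 2),
         rep(n + ne + seq_len(nf), 3))
  j <- c(seq_len(n), e[, 1], e[, 2], faces[, 1], faces[, 2], faces[, 3])
  x <- c(rep(1, n), rep(0.5, 2 * ne), rep(1 / 3, 3 * nf))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n + ne + nf, n))
}
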