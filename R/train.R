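# Training: dataset split, Adam, and the face_autoencoder model object.

#' Split a dataset into training / validation / test indices
#'
#' Sizes are `round(n * r / sum(r))` for each ratio component, with any
#' rounding remainder assigned to the training set; assignment is a seeded
#' shuffle.
#'
#' @param n Dataset size (>= 20).
#' @param ratio Numeric triple, default `c(17, 2, 1)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
split_dataset <- function(n, ratio = c(17, 2, 1), seed = 1) {
  if (n < 20L) stopf("split_dataset needs n >= 20")
  if (length(ratio) != 3L || any(ratio <= 0)) stopf("ratio must be 3 positive numbers")
  sizes <- round(n * ratio / sum(ratio))
  sizes[1] <- sizes[1] + (n - sum(sizes))
  if (any(sizes < 1L)) stopf("split would leave an empty set (sizes %s)",
                             paste(sizes, collapse = "/"))
  perm <- with_local_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1])]),
       val = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Training configuration
#'
#' @param lambda_reg Weight of the spherical latent regularization
#'   (default 0.01).
#' @param learning_rate Initial Adam learning rate (default 0.001).
#' @param epochs Maximum epochs (default 500).
#' @param batch_size Minibatch size (default 8).
#' @param split_ratio Train/validation/test ratio (default 17:2:1).
#' @param patience Early-stopping patience on the validation reconstruction
#'   loss, in epochs (default 50); `Inf` disables early stopping.
#' @param seed Integer seed governing the split, initialization and batch
#'   shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda_reg = 0.01, learning_rate = 0.001,
                         epochs = 500, batch_size = 8,
                         split_ratio = c(17, 2, 1), patience = 50,
                         seed = 1) {
  if (lambda_reg < 0) stopf("lambda_reg must be >= 0")
  structure(list(lambda_reg = lambda_reg, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size,
                 split_ratio = split_ratio, patience = patience,
                 seed = seed),
            class = "train_config")
}

# --- Adam over a nested parameter list --------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    return(Map(function(x, y) tree_map2(f, x, y), a, b))
  }
  f(a, b)
}

adam_init <- function(grads) {
  list(m = tree_map(function(g) g * 0, grads),
       v = tree_map(function(g) g * 0, grads), t = 0)
}

adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  step <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  theta <- tree_map2(`-`, theta, step)
  list(theta = theta, state = state)
}

# Forward + loss + backward for one stacked batch.  Returns recon (mm^2),
# reg (mean over batch), and parameter gradients for enc and dec.
train_batch_pass <- function(params, ops, X, B, lambda_reg) {
  n0 <- params$meta$sizes[1]
  Xn <- normalize_stack(params, X, B)
  enc <- fmgen_encode_fwd(params, ops, Xn)
  z <- enc$z
  dec <- fmgen_decode_fwd(params, ops, z)
  # internal objective: per-coordinate MSE on normalized coordinates plus
  # lambda * spherical penalty; the reported recon is the per-vertex squared
  # distance in mm^2 (same minimizer, interpretable scale)
  diffn <- dec$out_n - Xn
  recon <- sum(diffn * diffn) / (n0 * B) * params$norm$scale^2
  znorm <- sqrt(rowSums(z * z))
  reg <- mean((znorm - 1)^2)
  # gradients (internal objective divides the squared error by 3 * n0 * B)
  dout_n <- 2 * diffn / (3 * n0 * B)
  dreg_dz <- 2 * (znorm - 1) / pmax(znorm, 1e-12) / B * z
  bwd_dec <- fmgen_decode_bwd(params, ops, dec$cache, dout_n)
  dz <- bwd_dec$dz + lambda_reg * dreg_dz
  genc <- fmgen_encode_bwd(params, ops, enc$cache, dz)
  list(recon = recon, reg = reg, mean_znorm_dev = mean(abs(znorm - 1)),
       grads = list(enc = genc, dec = bwd_dec$grads))
}

# Reconstruction loss of a mesh set under current params (no gradients).
eval_recon <- function(params, graph, X, B, ops = NULL) {
  ops <- ops %||% batch_ops(graph, B)
  n0 <- params$meta$sizes[1]
  Xn <- normalize_stack(params, X, B)
  z <- fmgen_encode_fwd(params, ops, Xn)$z
  out_n <- fmgen_decode_fwd(params, ops, z)$out_n
  out <- denormalize_stack(params, out_n, B)
  d <- out - X
  sum(d * d) / (n0 * B)
}

#' Train the face autoencoder
#'
#' Unsupervised training (each face is its own target) of the dual-branch
#' graph-convolutional autoencoder by Adam, minimizing vertex-wise MSE plus
#' the spherical latent regularization.  The dataset is split into
#' train/validation/test sets; training tracks the validation
#' reconstruction loss, keeps the best parameters seen, and stops early
#' when validation stops improving.
#'
#' @param meshes List of [face_mesh()] objects sharing one topology.
#' @param graph Optional [build_face_graph()] hierarchy (built from the
#'   first mesh when omitted).
#' @param config A [train_config()].
#' @param latent_dim,widths,branch_width Architecture settings passed to
#'   [init_fmgen_params()].
#' @param verbose Print per-epoch progress every 25 epochs.
#' @return An object of class `face_autoencoder`: `params`, `graph`,
#'   `template` (first mesh, carrying the topology), `history` (data frame
#'   with per-epoch train/validation losses and mean `|  ||z|| - 1 |`),
#'   `split`, `config`, `best_epoch`.
#' @export
train_face_autoencoder <- function(meshes, graph = NULL, config = train_config(),
                                   latent_dim = 256, widths = c(16, 32, 64),
                                   branch_width = 64, verbose = FALSE) {
  n <- length(meshes)
  if (n < 20L) stopf("need at least 20 meshes to split 17:2:1")
  for (m in meshes[-1]) if (!same_topology(meshes[[1]], m))
    stopf("all meshes must share one topology")
  graph <- graph %||% build_face_graph(meshes[[1]], n_levels = 3)
  split <- split_dataset(n, config$split_ratio, seed = config$seed)
  params <- init_fmgen_params(graph, latent_dim = latent_dim, widths = widths,
                              branch_width = branch_width,
                              seed = derive_seed(config$seed, 1))
  # normalization from the training set: per-vertex mean face, global sd
  Xtr_list <- lapply(meshes[split$train], function(m) m$vertices)
  center <- Reduce(`+`, Xtr_list) / length(Xtr_list)
  resid <- vapply(Xtr_list, function(v) mean((v - center)^2), numeric(1))
  scale <- sqrt(max(mean(resid), 1e-8))
  params$norm <- list(center = center, scale = scale)
  params$template_faces <- meshes[[1]]$faces

  ntr <- length(split$train)
  bs <- min(config$batch_size, ntr)
  Xval <- stack_meshes(meshes[split$val])
  ops_val <- batch_ops(graph, length(split$val))
  ops_cache <- list()
  get_ops <- function(B) {
    key <- as.character(B)
    if (is.null(ops_cache[[key]])) ops_cache[[key]] <<- batch_ops(graph, B)
    ops_cache[[key]]
  }

  theta <- list(enc = params$enc, dec = params$dec)
  state <- NULL
  hist <- list()
  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  wait <- 0L

  with_local_seed(derive_seed(config$seed, 2), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(split$train)
      ep_recon <- ep_reg <- ep_zdev <- 0
      nb <- 0L
      for (start in seq(1, ntr, by = bs)) {
        ids <- ord[start:min(start + bs - 1L, ntr)]
        B <- length(ids)
        X <- stack_meshes(meshes[ids])
        params$enc <- theta$enc
        params$dec <- theta$dec
        pass <- train_batch_pass(params, get_ops(B), X, B, config$lambda_reg)
        if (!is.finite(pass$recon))
          stopf("training diverged at epoch %d (non-finite loss)", epoch)
        if (is.null(state)) state <- adam_init(pass$grads)
        upd <- adam_step(theta, pass$grads, state, lr = config$learning_rate)
        theta <- upd$theta
        state <- upd$state
        w <- B / ntr
        ep_recon <- ep_recon + w * pass$recon
        ep_reg <- ep_reg + w * pass$reg
        ep_zdev <- ep_zdev + w * pass$mean_znorm_dev
        nb <- nb + 1L
      }
      params$enc <- theta$enc
      params$dec <- theta$dec
      val <- eval_recon(params, graph, Xval, length(split$val), ops_val)
      hist[[epoch]] <- c(epoch = epoch, train_recon = ep_recon,
                         train_reg = ep_reg, train_total =
                           ep_recon + config$lambda_reg * ep_reg,
                         val_recon = val, mean_znorm_dev = ep_zdev)
      if (verbose && epoch %% 25 == 0)
        message(sprintf("epoch %4d  train %.4f  val %.4f  |z|-1 %.3f",
                        epoch, ep_recon, val, ep_zdev))
      if (val < best_val - 1e-10) {
        best_val <- val
        best_theta <- theta
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  params$enc <- best_theta$enc
  params$dec <- best_theta$dec
  history <- as.data.frame(do.call(rbind, hist))
  structure(list(params = params, graph = graph, template = meshes[[1]],
                 history = history, split = split, config = config,
                 best_epoch = best_epoch, best_val = best_val),
            class = "face_autoencoder")
}

#' Mean reconstruction MSE over a test set
#'
#' Mean over the given meshes of [recon_loss()] between each mesh and its
#' encode-decode reconstruction, in mm^2.
#'
#' @param model A fitted [train_face_autoencoder()] model.
#' @param meshes List of [face_mesh()] objects to evaluate.
#' @return Scalar mean MSE.
#' @export
test_mse <- function(model, meshes = NULL) {
  stopifnot(inherits(model, "face_autoencoder"))
  if (is.null(meshes)) stopf("supply the meshes to evaluate")
  mean(vapply(meshes, function(m) {
    recon_loss(m, predict(model, m))
  }, numeric(1)))
}

#' @export
print.face_autoencoder <- function(x, ...) {
  pc <- count_params(x$params)
  cat(sprintf("face_autoencoder: D = %d, %s vertices, %d + %d = %d parameters\n",
              x$params$meta$D, x$params$meta$sizes[1],
              pc["encoder"], pc["decoder"], pc["total"]))
  cat(sprintf("  trained %d epoch(s); best validation MSE %.4f mm^2 at epoch %d\n",
              nrow(x$history), x$best_val, x$best_epoch))
  invisible(x)
}

#' @export
summary.face_autoencoder <- function(object, ...) {
  h <- object$history
  cat("Graph-convolutional face autoencoder\n")
  print(object)
  cat(sprintf("  split: %d train / %d val / %d test\n",
              length(object$split$train), length(object$split$val),
              length(object$split$test)))
  cat(sprintf("  final train MSE %.4f mm^2, mean | ||z||-1 | %.4f\n",
              h$train_recon[nrow(h)], h$mean_znorm_dev[nrow(h)]))
  invisible(object)
}

#' Reconstruct meshes through the autoencoder
#'
#' @param object A fitted [train_face_autoencoder()] model.
#' @param newdata A [face_mesh()] or list of them.
#' @param ... Unused.
#' @return A reconstructed [face_mesh()] (or list of them).
#' @export
predict.face_autoencoder <- function(object, newdata, ...) {
  one <- function(m) decode(object, encode(object, m))
  if (inherits(newdata, "face_mesh")) one(newdata) else lapply(newdata, one)
}

#' Sample new faces from the trained generator
#'
#' Decodes latent vectors drawn uniformly on the unit hypersphere (the
#' region the spherical regularization concentrates training codes on).
#'
#' @param object A fitted [train_face_autoencoder()] model.
#' @param nsim Number of faces.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of [face_mesh()] objects.
#' @export
simulate.face_autoencoder <- function(object, nsim = 1, seed = 1, ...) {
  D <- object$params$meta$D
  zs <- with_local_seed(seed, {
    z <- matrix(stats::rnorm(nsim * D), nsim, D)
    z / sqrt(rowSums(z * z))
  })
  lapply(seq_len(nsim), function(i) decode(object, zs[i, ]))
}

#' Plot training history
#'
#' @param x A fitted [train_face_autoencoder()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.face_autoencoder <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_recon, h$val_recon), type = "l",
                    lty = 1, col = c("black", "firebrick"), log = "y",
                    xlab = "epoch", ylab = "reconstruction MSE (mm^2)", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
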