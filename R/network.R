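# Dual-branch graph-convolutional autoencoder: parameter containers,
# forward/backward passes, and the encode/decode user API.
#
# All passes operate on "stacked" batches: a batch of B meshes with n
# vertices is an (n*B) x F matrix, mesh b occupying rows (b-1)*n + 1 .. b*n.
# Per-level propagation/pool operators are lifted to a batch with
# kron(I_B, M), so every layer is one sparse-dense and one dense product,
# and the whole network stays inside BLAS.

lrelu <- function(x, slope) {
  # 0.5*(1+s)*x + 0.5*(1-s)*|x|: branch-free, no scattered assignment
  0.5 * (1 + slope) * x + 0.5 * (1 - slope) * abs(x)
}

dlrelu <- function(x, slope) {
  slope + (1 - slope) * (x > 0)
}

kron_block <- function(B, M) {
  if (B == 1L) return(M)
  methods::as(Matrix::kronecker(Matrix::Diagonal(B), M), "CsparseMatrix")
}

# Batch-lifted operators for a given batch size (cached by the training loop).
batch_ops <- function(graph, B) {
  lift <- function(M) kron_block(B, M)
  A <- lapply(graph$adj, lift)
  P <- lapply(graph$pools, lift)
  U <- lapply(graph$unpools, lift)
  n0 <- graph$sizes[1]
  nL <- graph$sizes[length(graph$sizes)]
  M0 <- kron_block(B, Matrix::Matrix(1 / n0, 1, n0, sparse = TRUE))
  ML <- kron_block(B, Matrix::Matrix(1 / nL, 1, nL, sparse = TRUE))
  list(A = A, tA = lapply(A, Matrix::t),
       P = P, tP = lapply(P, Matrix::t),
       U = U, tU = lapply(U, Matrix::t),
       M0 = M0, tM0 = Matrix::t(M0),
       ML = ML, tML = Matrix::t(ML),
       B = B)
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialize autoencoder parameters
#'
#' Seeded Glorot-uniform initialization of the dual-branch encoder (a global
#' branch of three graph-conv/activation/pool stages and a local branch of
#' three graph-conv/activation stages, each mean-pooled and passed through a
#' linear layer, fused by one linear map to the latent space) and the decoder
#' (a linear latent-to-coarse-vertex embedding, copied up the pooling
#' hierarchy through two graph-conv/activation stages and a final graph-conv
#' emitting 3 coordinates per vertex).  All activations are leaky-ReLU.
#'
#' @param graph A [build_face_graph()] hierarchy (3 levels for the default
#'   architecture).
#' @param latent_dim Latent dimension D (default 256).
#' @param widths Feature widths of the three conv stages (default 16, 32, 64).
#' @param branch_width Width of each branch's linear output (default 64).
#' @param slope Leaky-ReLU negative slope (default 0.01).
#' @param seed Integer seed.
#' @return An object of class `fmgen_params`.
#' @export
init_fmgen_params <- function(graph, latent_dim = 256, widths = c(16, 32, 64),
                              branch_width = 64, slope = 0.01, seed = 1) {
  if (graph$n_levels < 3L) stopf("the default architecture needs >= 3 pooling levels")
  if (length(widths) != 3L) stopf("widths must have length 3")
  n0 <- graph$sizes[1]
  nL <- graph$sizes[graph$n_levels + 1L]
  Fw <- widths; H <- branch_width; D <- latent_dim
  G <- rev(Fw)
  with_local_seed(seed, {
    conv <- function(fin, fout) list(W = glorot(fin, fout), b = numeric(fout))
    params <- list(
      enc = list(
        global = list(conv = list(conv(3, Fw[1]), conv(Fw[1], Fw[2]),
                                  conv(Fw[2], Fw[3])),
                      lin = conv(nL * Fw[3], H)),
        local = list(conv = list(conv(3, Fw[1]), conv(Fw[1], Fw[2]),
                                 conv(Fw[2], Fw[3])),
                     lin = conv(Fw[3], H)),
        fuse = conv(2 * H, D)),
      dec = list(lin = conv(D, nL * G[1]),
                 conv = list(conv(G[1], G[2]), conv(G[2], G[3]),
                             conv(G[3], 3))),
      norm = list(center = matrix(0, n0, 3), scale = 1),
      meta = list(D = D, widths = Fw, branch_width = H, slope = slope,
                  sizes = graph$sizes, n_levels = graph$n_levels,
                  topology_id = graph$topology_id, seed = seed))
    # zero-initialized latent head: the code scale is established during
    # training by the data and the spherical regularizer, not by the
    # initialization gain of the 2H-wide fusion input
    params$enc$fuse$W[] <- 0
    class(params) <- "fmgen_params"
    params
  })
}

#' Number of trainable parameters
#' @param params An `fmgen_params` object.
#' @return Named numeric vector with `encoder`, `decoder` and `total` counts.
#' @export
count_params <- function(params) {
  cnt <- function(x) {
    if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  }
  enc <- cnt(params$enc)
  dec <- cnt(params$dec)
  c(encoder = enc, decoder = dec, total = enc + dec)
}

# (B x nL*G1) row-per-mesh  ->  (nL*B x G1) stacked
latent_rows_to_stack <- function(h, nL, G1) {
  B <- nrow(h)
  do.call(rbind, lapply(seq_len(B), function(b) matrix(h[b, ], nL, G1)))
}

latent_stack_to_rows <- function(hs, nL, G1) {
  B <- nrow(hs) / nL
  t(vapply(seq_len(B), function(b)
    as.numeric(hs[(b - 1L) * nL + seq_len(nL), , drop = FALSE]),
    numeric(nL * G1)))
}

# --- encoder ----------------------------------------------------------------

fmgen_encode_fwd <- function(params, ops, Xn) {
  s <- params$meta$slope
  cache <- list(Xn = Xn)
  # global branch
  h <- Xn
  for (i in 1:3) {
    C <- as.matrix(ops$A[[i]] %*% h)
    Z <- C %*% params$enc$global$conv[[i]]$W +
      rep(params$enc$global$conv[[i]]$b, each = nrow(C))
    Aact <- lrelu(Z, s)
    cache[[paste0("gC", i)]] <- C
    cache[[paste0("gZ", i)]] <- Z
    h <- as.matrix(ops$P[[i]] %*% Aact)
    cache[[paste0("gA", i)]] <- Aact
  }
  # flatten the coarsest-level features (spatial layout preserved)
  nL <- params$meta$sizes[params$meta$n_levels + 1L]
  F3 <- params$meta$widths[3]
  gm <- latent_stack_to_rows(h, nL, F3)
  gh <- gm %*% params$enc$global$lin$W +
    rep(params$enc$global$lin$b, each = nrow(gm))
  cache$gtop <- h; cache$gm <- gm
  # local branch
  h <- Xn
  for (i in 1:3) {
    C <- as.matrix(ops$A[[1]] %*% h)
    Z <- C %*% params$enc$local$conv[[i]]$W +
      rep(params$enc$local$conv[[i]]$b, each = nrow(C))
    h <- lrelu(Z, s)
    cache[[paste0("lC", i)]] <- C
    cache[[paste0("lZ", i)]] <- Z
  }
  lm <- as.matrix(ops$M0 %*% h)
  lh <- lm %*% params$enc$local$lin$W +
    rep(params$enc$local$lin$b, each = nrow(lm))
  cache$lm <- lm
  fused_in <- cbind(gh, lh)
  z <- fused_in %*% params$enc$fuse$W +
    rep(params$enc$fuse$b, each = nrow(fused_in))
  cache$fused_in <- fused_in
  list(z = z, cache = cache)
}

fmgen_encode_bwd <- function(params, ops, cache, dz) {
  s <- params$meta$slope
  H <- params$meta$branch_width
  g <- list(global = list(conv = vector("list", 3)),
            local = list(conv = vector("list", 3)))
  g$fuse <- list(W = t(cache$fused_in) %*% dz, b = colSums(dz))
  dfused <- dz %*% t(params$enc$fuse$W)
  dgh <- dfused[, seq_len(H), drop = FALSE]
  dlh <- dfused[, H + seq_len(H), drop = FALSE]
  # global branch
  g$global$lin <- list(W = t(cache$gm) %*% dgh, b = colSums(dgh))
  dgm <- dgh %*% t(params$enc$global$lin$W)
  nL <- params$meta$sizes[params$meta$n_levels + 1L]
  dh <- latent_rows_to_stack(dgm, nL, params$meta$widths[3])
  for (i in 3:1) {
    dA <- as.matrix(ops$tP[[i]] %*% dh)
    dZ <- dA * dlrelu(cache[[paste0("gZ", i)]], s)
    g$global$conv[[i]] <- list(W = t(cache[[paste0("gC", i)]]) %*% dZ,
                               b = colSums(dZ))
    if (i > 1)
      dh <- as.matrix(ops$tA[[i]] %*%
                        (dZ %*% t(params$enc$global$conv[[i]]$W)))
  }
  # local branch
  g$local$lin <- list(W = t(cache$lm) %*% dlh, b = colSums(dlh))
  dlm <- dlh %*% t(params$enc$local$lin$W)
  dh <- as.matrix(ops$tM0 %*% dlm)
  for (i in 3:1) {
    dZ <- dh * dlrelu(cache[[paste0("lZ", i)]], s)
    g$local$conv[[i]] <- list(W = t(cache[[paste0("lC", i)]]) %*% dZ,
                              b = colSums(dZ))
    if (i > 1)
      dh <- as.matrix(ops$tA[[1]] %*%
                        (dZ %*% t(params$enc$local$conv[[i]]$W)))
  }
  g
}

# --- decoder ----------------------------------------------------------------

fmgen_decode_fwd <- function(params, ops, z) {
  s <- params$meta$slope
  nl <- params$meta$n_levels
  nL <- params$meta$sizes[nl + 1L]
  G1 <- rev(params$meta$widths)[1]
  cache <- list(z = z)
  hrows <- z %*% params$dec$lin$W + rep(params$dec$lin$b, each = nrow(z))
  hs <- latent_rows_to_stack(hrows, nL, G1)
  h <- as.matrix(ops$U[[3]] %*% hs)           # level 2
  cache$hs <- hs
  lev <- c(3, 2, 1)                            # adjacency index per conv
  for (i in 1:3) {
    C <- as.matrix(ops$A[[lev[i]]] %*% h)
    Z <- C %*% params$dec$conv[[i]]$W +
      rep(params$dec$conv[[i]]$b, each = nrow(C))
    cache[[paste0("dC", i)]] <- C
    cache[[paste0("dZ", i)]] <- Z
    if (i < 3) {
      Aact <- lrelu(Z, s)
      h <- as.matrix(ops$U[[lev[i + 1]]] %*% Aact)
    }
  }
  list(out_n = cache$dZ3, cache = cache)       # final conv: no activation
}

fmgen_decode_bwd <- function(params, ops, cache, dout_n,
                             param_grads = TRUE) {
  s <- params$meta$slope
  nl <- params$meta$n_levels
  nL <- params$meta$sizes[nl + 1L]
  G1 <- rev(params$meta$widths)[1]
  g <- list(conv = vector("list", 3))
  lev <- c(3, 2, 1)
  dZ <- dout_n
  for (i in 3:1) {
    if (param_grads)
      g$conv[[i]] <- list(W = t(cache[[paste0("dC", i)]]) %*% dZ,
                          b = colSums(dZ))
    dh <- as.matrix(ops$tA[[lev[i]]] %*% (dZ %*% t(params$dec$conv[[i]]$W)))
    if (i > 1) {
      dA <- as.matrix(ops$tU[[lev[i]]] %*% dh)
      dZ <- dA * dlrelu(cache[[paste0("dZ", i - 1)]], s)
    } else {
      dhs <- as.matrix(ops$tU[[3]] %*% dh)
    }
  }
  dhrows <- latent_stack_to_rows(dhs, nL, G1)
  if (param_grads)
    g$lin <- list(W = t(cache$z) %*% dhrows, b = colSums(dhrows))
  dz <- dhrows %*% t(params$dec$lin$W)
  list(grads = if (param_grads) g else NULL, dz = dz)
}

# --- normalization and user-facing API --------------------------------------

stack_meshes <- function(meshes) {
  do.call(rbind, lapply(meshes, function(m) m$vertices))
}

normalize_stack <- function(params, X, B) {
  ctr <- params$norm$center
  (X - ctr[rep(seq_len(nrow(ctr)), B), , drop = FALSE]) / params$norm$scale
}

denormalize_stack <- function(params, Xn, B) {
  ctr <- params$norm$center
  Xn * params$norm$scale + ctr[rep(seq_len(nrow(ctr)), B), , drop = FALSE]
}

#' Encode a face into the latent space
#'
#' @param model An `fmgen_params` object or a fitted
#'   [train_face_autoencoder()] model (in which case `graph` is taken from
#'   it).
#' @param x A [face_mesh()] on the template topology.
#' @param graph The [build_face_graph()] hierarchy the parameters were built
#'   for (required with raw parameters).
#' @return Numeric latent vector of length `D`.
#' @export
encode <- function(model, x, graph = NULL) {
  if (inherits(model, "face_autoencoder")) {
    graph <- graph %||% model$graph
    params <- model$params
  } else params <- model
  if (!identical(params$meta$topology_id, x$topology_id) ||
      nrow(x$vertices) != params$meta$sizes[1])
    stopf("mesh topology does not match the model ('%s' vs '%s')",
          x$topology_id, params$meta$topology_id)
  ops <- batch_ops(graph, 1L)
  Xn <- normalize_stack(params, x$vertices, 1L)
  as.numeric(fmgen_encode_fwd(params, ops, Xn)$z)
}

#' Decode a latent vector into a face mesh
#'
#' @inheritParams encode
#' @param z Numeric latent vector of length `D`.
#' @param faces Face array for the output mesh (template faces); required
#'   when calling with raw parameters, taken from the model otherwise.
#' @return A [face_mesh()] on the template topology.
#' @export
decode <- function(model, z, graph = NULL, faces = NULL) {
  if (inherits(model, "face_autoencoder")) {
    graph <- graph %||% model$graph
    faces <- faces %||% model$template$faces
    params <- model$params
  } else params <- model
  faces <- faces %||% params$template_faces
  if (is.null(faces)) stopf("decode needs the template face array")
  if (length(z) != params$meta$D)
    stopf("latent vector has length %d; model D = %d", length(z), params$meta$D)
  ops <- batch_ops(graph, 1L)
  out_n <- fmgen_decode_fwd(params, ops, matrix(z, 1))$out_n
  face_mesh(denormalize_stack(params, out_n, 1L), faces,
            topology_id = params$meta$topology_id)
}
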