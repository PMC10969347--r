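# Autoencoder contracts: losses, shapes, determinism, differentiability.

test_that("loss identities hold", {
  tpl <- tiny_template()
  m1 <- tpl$mesh
  m2 <- m1
  expect_equal(recon_loss(m1, m1), 0)
  # uniform (1,0,0) offset: every squared vertex distance is exactly 1
  m2$vertices <- m1$vertices + matrix(c(1, 0, 0), nrow(m1$vertices), 3,
                                      byrow = TRUE)
  expect_identical(recon_loss(m1, m2), 1)
  # symmetry and positivity
  set.seed(1)
  m3 <- m1
  m3$vertices <- m1$vertices + matrix(rnorm(length(m1$vertices)), ncol = 3)
  expect_equal(recon_loss(m1, m3), recon_loss(m3, m1))
  expect_gt(recon_loss(m1, m3), 0)
  # direct double-precision recomputation
  expect_equal(recon_loss(m1, m3),
               mean(rowSums((m1$vertices - m3$vertices)^2)))

  z <- c(3, 4) / 5
  expect_equal(reg_loss(z), 0)
  expect_equal(reg_loss(rep(0, 8)), 1)
  expect_equal(reg_loss(c(3, 0, 0)), 4)

  expect_equal(total_loss(m1, m3, z, lambda_reg = 0), recon_loss(m1, m3))
  expect_equal(total_loss(m1, m1, z, 0.5), 0)
  lam <- 0.01
  expect_equal(total_loss(m1, m3, c(3, 0, 0), lam),
               recon_loss(m1, m3) + lam * 4, tolerance = 1e-12)
})

test_that("paper hyperparameter defaults are preserved", {
  cfg <- train_config()
  expect_equal(cfg$lambda_reg, 0.01)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$split_ratio, c(17, 2, 1))
  p <- formals(init_fmgen_params)
  expect_equal(p$latent_dim, 256)
})

test_that("split_dataset sizes follow the rounding rule and the seeded shuffle", {
  s <- split_dataset(400, c(17, 2, 1), seed = 1)
  expect_equal(lengths(s), c(train = 340L, val = 40L, test = 20L))
  s2 <- split_dataset(40, c(17, 2, 1), seed = 1)
  expect_equal(lengths(s2), c(train = 34L, val = 4L, test = 2L))
  expect_identical(split_dataset(60, seed = 5), split_dataset(60, seed = 5))
  all_ids <- sort(unlist(split_dataset(53, seed = 2)))
  expect_identical(all_ids, 1:53, ignore_attr = TRUE)
  expect_error(split_dataset(10), "n >= 20")
})

test_that("encode/decode satisfy shape, determinism and topology contracts", {
  tpl <- tiny_template()
  gr <- build_face_graph(tpl$mesh, n_levels = 3)
  params <- init_fmgen_params(gr, latent_dim = 16, widths = c(4, 8, 16),
                              branch_width = 16, seed = 2)
  params$template_faces <- tpl$mesh$faces
  z <- encode(params, tpl$mesh, graph = gr)
  expect_length(z, 16)
  expect_true(all(is.finite(z)))
  expect_identical(encode(params, tpl$mesh, graph = gr), z)
  m <- decode(params, z, graph = gr)
  expect_s3_class(m, "face_mesh")
  expect_identical(m$faces, tpl$mesh$faces)
  expect_identical(decode(params, z, graph = gr)$vertices, m$vertices)
  expect_error(decode(params, z[1:5], graph = gr), "length")
  bad <- grid_sheet(6)
  expect_error(encode(params, bad, graph = gr), "topology")
})

test_that("decoder is differentiable in z: analytic gradient matches finite differences", {
  tpl <- tiny_template()
  gr <- build_face_graph(tpl$mesh, n_levels = 3)
  params <- init_fmgen_params(gr, latent_dim = 12, widths = c(4, 8, 16),
                              branch_width = 16, seed = 3)
  ops <- nasorecon:::batch_ops(gr, 1L)
  set.seed(4)
  z <- rnorm(12)
  fwd <- nasorecon:::fmgen_decode_fwd(params, ops, matrix(z, 1))
  n <- nrow(fwd$out_n)
  dout <- matrix(0, n, 3)
  dout[, 1] <- 1 / n   # objective: mean vertex x-coordinate
  dz <- as.numeric(nasorecon:::fmgen_decode_bwd(params, ops, fwd$cache, dout,
                                                param_grads = FALSE)$dz)
  h <- 1e-5
  for (k in c(1L, 5L, 12L)) {
    zp <- z; zp[k] <- zp[k] + h
    zm <- z; zm[k] <- zm[k] - h
    fd <- (mean(nasorecon:::fmgen_decode_fwd(params, ops, matrix(zp, 1))$out_n[, 1]) -
           mean(nasorecon:::fmgen_decode_fwd(params, ops, matrix(zm, 1))$out_n[, 1])) / (2 * h)
    expect_equal(dz[k], fd, tolerance = 1e-4)
  }
})

test_that("a short training run reduces the loss on a tiny population", {
  tpl <- tiny_template()
  pop <- population_model(tpl, K = 2, scales = c(2, 1), seed = 6)
  faces <- sample_population(tpl, pop, 24, seed = 7)
  gr <- build_face_graph(tpl$mesh, n_levels = 3)
  mod <- train_face_autoencoder(
    faces, gr, train_config(epochs = 40, patience = 40, seed = 8),
    latent_dim = 8, widths = c(4, 8, 16), branch_width = 16)
  h <- mod$history
  expect_lt(h$train_recon[nrow(h)], h$train_recon[1])
  expect_true(all(is.finite(h$val_recon)))
  # determinism of the whole training given the seed
  mod2 <- train_face_autoencoder(
    faces, gr, train_config(epochs = 40, patience = 40, seed = 8),
    latent_dim = 8, widths = c(4, 8, 16), branch_width = 16)
  expect_identical(mod$history, mod2$history)
  expect_identical(mod$params$enc$fuse$W, mod2$params$enc$fuse$W)
  # test_mse equals mean recon loss of encode-decode reconstructions
  tm <- test_mse(mod, faces[mod$split$test])
  manual <- mean(vapply(faces[mod$split$test], function(m)
    recon_loss(m, predict(mod, m)), numeric(1)))
  expect_equal(tm, manual)
  # model methods run
  expect_output(print(mod), "face_autoencoder")
  sims <- simulate(mod, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "face_mesh")
})
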