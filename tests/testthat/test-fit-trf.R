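# Latent/rigid fitting against a small trained model.  One model is trained
# once per test run and shared across the blocks below.

fit_fixture <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    tpl <- tiny_template()
    pop <- population_model(tpl, K = 4, scales = c(2.5, 1.5, 1, 0.5), seed = 21)
    faces <- sample_population(tpl, pop, 30, seed = 22)
    gr <- build_face_graph(tpl$mesh, n_levels = 3)
    mod <- train_face_autoencoder(
      faces, gr, train_config(epochs = 120, patience = 120, seed = 23),
      latent_dim = 8, widths = c(4, 8, 16), branch_width = 16)
    val <<- list(tpl = tpl, pop = pop, faces = faces, mod = mod)
    val
  }
})

test_that("self-consistency: a defect cut from decode(z0), initialized at z0, starts at chamfer 0", {
  fx <- fit_fixture()
  D <- fx$mod$params$meta$D
  z0 <- local({ set.seed(30); v <- rnorm(D); 1.3 * v / sqrt(sum(v^2)) })
  gen <- decode(fx$mod, z0)
  def <- simulate_defect(gen, fx$tpl, source_id = "gen")
  cfg <- fit_config(max_iters = 5, restarts = 1, lambda_reg = 0.01)
  fit <- fit_trf(def, fx$mod, cfg, z_init = z0, template = fx$tpl)
  expect_equal(fit$objective_history[1], 0.01 * reg_loss(z0), tolerance = 1e-10)
})

test_that("objective history is finite and its minimum is the reported final objective", {
  fx <- fit_fixture()
  def <- simulate_defect(sample_population(fx$tpl, fx$pop, 1, seed = 77)[[1]],
                         fx$tpl)
  fit <- fit_trf(def, fx$mod, fit_config(max_iters = 60, restarts = 2),
                 template = fx$tpl)
  expect_true(all(is.finite(fit$objective_history)))
  expect_equal(min(fit$objective_history), fit$final_objective)
  expect_identical(nrow(fit$trf$vertices), nrow(fx$tpl$mesh$vertices))
  # trf = transform applied to decode(z_star)
  rebuilt <- apply_rigid(decode(fx$mod, fit$z_star)$vertices,
                         fit$transform_star)
  expect_lt(max(abs(rebuilt - fit$trf$vertices)), 1e-9)
  # reproducibility with the same seeds
  fit2 <- fit_trf(def, fx$mod, fit_config(max_iters = 60, restarts = 2),
                  template = fx$tpl)
  expect_identical(fit$objective_history, fit2$objective_history)
})

test_that("rigid recovery: frozen-z fit recovers a known transform", {
  fx <- fit_fixture()
  D <- fx$mod$params$meta$D
  z0 <- local({ set.seed(31); v <- rnorm(D); v / sqrt(sum(v^2)) })
  gen <- decode(fx$mod, z0)
  def0 <- simulate_defect(gen, fx$tpl, source_id = "gen")
  moved <- apply_random_rigid(def0$mesh, seed = 41, max_angle_deg = 25,
                              max_translation = 15)
  cfg <- fit_config(max_iters = 250, restarts = 2, lambda_reg = 0,
                    optimize = c("rotation", "translation"))
  fit <- fit_trf(moved$mesh, fx$mod, cfg, z_init = z0)
  ang <- nasorecon:::rotation_angle_between(fit$transform_star$rotation,
                                            moved$transform$rotation)
  terr <- sqrt(sum((fit$transform_star$translation -
                      moved$transform$translation)^2))
  expect_lt(ang, 1)
  expect_lt(terr, 0.1)
})

test_that("the spherical penalty keeps the fitted code nearer the unit sphere", {
  fx <- fit_fixture()
  def <- simulate_defect(sample_population(fx$tpl, fx$pop, 1, seed = 88)[[1]],
                         fx$tpl)
  z_init <- local({ set.seed(55); v <- rnorm(fx$mod$params$meta$D)
                    v / sqrt(sum(v^2)) })
  fit_reg <- fit_trf(def, fx$mod,
                     fit_config(max_iters = 120, restarts = 1,
                                lambda_reg = 0.01),
                     z_init = z_init, template = fx$tpl)
  fit_off <- fit_trf(def, fx$mod,
                     fit_config(max_iters = 120, restarts = 1, lambda_reg = 0),
                     z_init = z_init, template = fx$tpl)
  dev_reg <- abs(sqrt(sum(fit_reg$z_star^2)) - 1)
  dev_off <- abs(sqrt(sum(fit_off$z_star^2)) - 1)
  expect_lte(dev_reg, dev_off + 1e-8)
  # and the code does not fly off the sphere from an on-sphere start
  expect_lte(dev_reg, 0.5)
})

test_that("fitting a held-out face beats the untransformed template baseline", {
  fx <- fit_fixture()
  face <- sample_population(fx$tpl, fx$pop, 1, seed = 99)[[1]]
  def <- simulate_defect(face, fx$tpl)
  fit <- fit_trf(def, fx$mod, fit_config(max_iters = 200, restarts = 1),
                 template = fx$tpl)
  baseline <- chamfer_unidirectional(def$mesh$vertices, fx$tpl$mesh$vertices)
  expect_lt(fit$final_objective, baseline)
})

test_that("invalid configurations are rejected", {
  expect_error(fit_config(max_iters = 0), "max_iters")
  expect_error(fit_config(convergence_tol = 0), "convergence_tol")
  expect_error(fit_config(optimize = "scale"), "unknown optimize")
})
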