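test_that("the template is deterministic, bilaterally symmetric, and fully labelled", {
  tpl <- make_template(32)
  tpl2 <- make_template(32)
  expect_identical(tpl$mesh$vertices, tpl2$mesh$vertices)
  expect_identical(tpl$mesh$faces, tpl2$mesh$faces)
  g <- 32
  v <- tpl$mesh$vertices[seq_len(g * g), ]
  # mirror about x = 0: column i pairs with column g + 1 - i
  perm <- unlist(lapply(seq_len(g), function(j) (j - 1) * g + (g:1)))
  mir <- v[perm, ]
  mir[, 1] <- -mir[, 1]
  expect_lt(max(abs(v - mir)), 1e-9)
  # all nine subunits present and mutually exclusive
  labs <- as.character(tpl$region_labels[tpl$nose_mask])
  expect_setequal(unique(labs), NASAL_SUBUNITS)
  expect_false(any(tpl$region_labels[!tpl$nose_mask] != "non_nasal"))
})

test_that("removing the nose leaves exactly one boundary loop", {
  tpl <- tiny_template()
  def <- submesh(tpl$mesh, !tpl$nose_mask)
  expect_s3_class(extract_boundary(def), "boundary_curve")
})

test_that("population sampling is seeded and matches its closed-form variance", {
  tpl <- tiny_template()
  pop <- population_model(tpl, K = 4, scales = c(3, 2, 1, 0.5), seed = 3)
  a <- sample_population(tpl, pop, 5, seed = 9)
  b <- sample_population(tpl, pop, 5, seed = 9)
  for (i in 1:5) expect_identical(a[[i]]$vertices, b[[i]]$vertices)
  expect_true(all(vapply(a, function(m)
    identical(m$topology_id, tpl$mesh$topology_id), logical(1))))

  # Monte-Carlo per-vertex variance vs sum_k scale_k^2 basis_k^2
  n <- 400
  s <- sample_population(tpl, pop, n, seed = 10)
  X <- vapply(s, function(m) as.numeric(m$vertices),
              numeric(length(tpl$mesh$vertices)))
  vhat <- apply(X, 1, stats::var)
  vtheory <- Reduce(`+`, Map(function(sc, b) sc^2 * as.numeric(b)^2,
                             pop$scales, pop$basis))
  # aggregate comparison (per-entry MC error is large at n = 400)
  expect_equal(mean(vhat), mean(vtheory), tolerance = 0.1)
  expect_gt(stats::cor(vhat, vtheory), 0.9)
})

test_that("zero scales give degenerate samples identical to the template", {
  tpl <- tiny_template()
  pop <- population_model(tpl, K = 2, scales = c(0, 0), seed = 1)
  s <- sample_population(tpl, pop, 3, seed = 2)
  for (m in s) expect_equal(m$vertices, tpl$mesh$vertices, ignore_attr = TRUE)
})

test_that("basis fields are spatially smooth and oversized scales are rejected", {
  tpl <- tiny_template()
  pop <- population_model(tpl, seed = 4)
  expect_lt(pop$smoothness, 1.5)  # per-edge jump bound, unit-RMS fields
  expect_error(population_model(tpl, K = 2, scales = c(50, 50)),
               "bounding-box")
})

test_that("simulate_defect deletes the nose without moving surviving vertices", {
  tpl <- tiny_template()
  pop <- population_model(tpl, K = 4, scales = c(3, 2, 1, 0.5), seed = 5)
  face <- sample_population(tpl, pop, 1, seed = 6)[[1]]
  def <- simulate_defect(face, tpl, source_id = "f1")
  expect_equal(nrow(def$mesh$vertices),
               nrow(face$vertices) - sum(tpl$nose_mask))
  # partition of the vertex set
  keep <- attr(def$mesh, "orig_index")
  nose <- attr(def$nose_original, "orig_index")
  expect_setequal(c(keep, nose), seq_len(nrow(face$vertices)))
  # deletion only: coordinates unchanged
  expect_identical(def$mesh$vertices, face$vertices[keep, ])
  expect_identical(def$nose_original$vertices, face$vertices[nose, ])
  # defect rim length equals the template's nose-boundary loop length
  tpl_def <- simulate_defect(tpl$mesh, tpl)
  expect_equal(nrow(def$defect_curve$points), nrow(tpl_def$defect_curve$points))
  # identity source: nose_original is the template nose submesh
  expect_identical(tpl_def$nose_original$vertices,
                   tpl$mesh$vertices[tpl$nose_mask, ])
  expect_error(simulate_defect(grid_sheet(6), tpl), "topology")
})

test_that("apply_random_rigid is seeded, invertible, and respects the identity config", {
  m <- tiny_template()$mesh
  a <- apply_random_rigid(m, seed = 7)
  b <- apply_random_rigid(m, seed = 7)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  back <- apply_rigid(a$mesh$vertices, a$transform, inverse = TRUE)
  expect_lt(max(abs(back - m$vertices)), 1e-9)
  ident <- apply_random_rigid(m, seed = 1, max_angle_deg = 0, max_translation = 0)
  expect_equal(ident$mesh$vertices, m$vertices, ignore_attr = TRUE)
  ang <- sqrt(sum(a$transform$axis_angle^2)) * 180 / pi
  expect_lte(ang, 30)
  expect_lte(sqrt(sum(a$transform$translation^2)), 20)
})
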