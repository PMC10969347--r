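test_that("surface deviation of identical meshes is zero and of a plane offset equals d", {
  m <- grid_sheet(6)
  expect_equal(surface_deviation(m, m)$rmsd, 0)
  off <- m
  d <- 2.5
  off$vertices[, 3] <- off$vertices[, 3] + d
  dev <- surface_deviation(off, m)
  expect_equal(dev$rmsd, d, tolerance = 1e-9)
  expect_equal(dev$max_deviation, d, tolerance = 1e-9)
})

test_that("surface deviation per-point distances equal the brute-force oracle", {
  a <- random_mesh(g = 6, seed = 21, jitter = 0.2)
  b <- random_mesh(g = 6, seed = 22, jitter = 0.2)
  dev <- surface_deviation(a, b)
  expect_equal(dev$per_point, mesh_dist_oracle(a$vertices, b), tolerance = 1e-12)
  expect_equal(dev$rmsd, sqrt(mean(dev$per_point^2)), tolerance = 1e-9)
  expect_equal(dev$max_deviation, max(dev$per_point))
  expect_lte(dev$rmsd, dev$max_deviation)
})

test_that("surface deviation is directional (asymmetric fixture)", {
  # reference: big sheet; test: small sheet far from the rim of the big one.
  big <- grid_sheet(9)
  small <- submesh(grid_sheet(9), c(1, 2, 10, 11))
  small$vertices[, 3] <- 1
  d1 <- surface_deviation(small, big)$rmsd   # every small vertex 1 away
  d2 <- surface_deviation(big, small)$rmsd   # far corners of big dominate
  expect_equal(d1, 1, tolerance = 1e-9)
  expect_gt(d2, d1)
})

test_that("deviation statistics are invariant under a common rigid transform", {
  a <- random_mesh(g = 6, seed = 31, jitter = 0.2)
  b <- random_mesh(g = 6, seed = 32, jitter = 0.2)
  base <- surface_deviation(a, b)
  tr <- rigid_transform(axis_angle = c(0.4, 0.1, -0.3), translation = c(9, -4, 2))
  a2 <- a; a2$vertices <- apply_rigid(a$vertices, tr)
  b2 <- b; b2$vertices <- apply_rigid(b$vertices, tr)
  moved <- surface_deviation(a2, b2)
  expect_equal(moved$rmsd, base$rmsd, tolerance = 1e-9)
  expect_equal(moved$max_deviation, base$max_deviation, tolerance = 1e-9)
})

test_that("the max surface deviation is localized to the right subunit", {
  tpl <- tiny_template()
  def <- simulate_defect(tpl$mesh, tpl)
  nose <- def$nose_original
  labs <- attr(nose, "region_labels")
  bumped <- nose
  itip <- which(labs == "nasal_tip")[1]
  bumped$vertices[itip, 3] <- bumped$vertices[itip, 3] + 4
  dev <- surface_deviation(bumped, nose, subunits = labs)
  expect_equal(dev$max_label, "nasal_tip")
  expect_equal(dev$max_deviation, 4, tolerance = 0.2)
})

test_that("curve deviation: identical curves give zero; concentric squares give d*sqrt(2) at corners", {
  sq <- function(s) boundary_curve(rbind(c(-s, -s, 0), c(s, -s, 0),
                                         c(s, s, 0), c(-s, s, 0)),
                                   closed = TRUE)
  expect_equal(curve_deviation(sq(1), sq(1), 64)$rmsd, 0)
  d <- 0.5
  dev <- curve_deviation(sq(1 + d), sq(1), n_samples = 400)
  expect_equal(dev$max_deviation, d * sqrt(2), tolerance = 1e-3)
  # dense brute-force oracle for the RMSD
  a <- nasorecon:::resample_closed_curve(sq(1 + d)$points, 400)
  dd <- nasorecon:::dist_to_polyline(a, nasorecon:::resample_closed_curve(sq(1)$points, 4000))
  expect_equal(dev$rmsd, sqrt(mean(dd^2)), tolerance = 1e-3)
  expect_error(curve_deviation(sq(1), boundary_curve(sq(1)$points, closed = FALSE),
                               64), "closed")
  expect_error(curve_deviation(sq(1), sq(1), 4), "n_samples")
})

test_that("curve deviation converges as sampling is refined", {
  set.seed(2)
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  c1 <- boundary_curve(cbind(2 * cos(ang), 2 * sin(ang), 0), closed = TRUE)
  c2 <- boundary_curve(cbind(2.4 * cos(ang), 2.1 * sin(ang), 0.2), closed = TRUE)
  r1 <- curve_deviation(c1, c2, 100)$rmsd
  r2 <- curve_deviation(c1, c2, 200)$rmsd
  r3 <- curve_deviation(c1, c2, 800)$rmsd
  expect_lt(abs(r2 - r3), 0.01)
  expect_lt(abs(r1 - r3), 0.02)
})

test_that("summarize_deviations computes mean, sample SD and a conserved tally", {
  mk <- function(rmsd, mx, lab) structure(
    list(rmsd = rmsd, max_deviation = mx, max_label = lab,
         per_point = c(rmsd)), class = "deviation_report")
  s <- summarize_deviations(list(mk(1, 2, "nasal_tip"), mk(1, 2, "nasal_ala_L"),
                                 mk(1, 2, "nasal_tip")))
  expect_equal(s$rmsd_mean, 1)
  expect_equal(s$rmsd_sd, 0)
  s2 <- summarize_deviations(list(mk(1, 4, "nasal_tip"), mk(3, 2, "nasal_ala_R")))
  expect_equal(s2$rmsd_mean, 2)
  expect_equal(s2$rmsd_sd, sqrt(2))
  expect_equal(sum(s$subunit_tally), 3)
  expect_equal(unname(s$subunit_tally["nasal_tip"]), 2)
  expect_error(summarize_deviations(list(mk(1, 2, "x"))), "at least 2")
})
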