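test_that("OBJ reading follows the 1-based index convention and ignores texture indices", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  m <- read_obj(path)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(m$faces, matrix(c(1L, 2L, 3L), 1))

  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1/1/1 2/2/2 3/3/3"), path)
  m2 <- read_obj(path)
  expect_equal(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices)
})

test_that("OBJ write/read round-trip preserves topology exactly and coordinates to printed precision", {
  m <- random_mesh(g = 7, seed = 42)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, path)
  m2 <- read_obj(path)
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("polygon faces are fan-triangulated and malformed records error", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), path)
  m <- read_obj(path)
  expect_equal(nrow(m$faces), 2L)
  expect_equal(m$faces[1, ], c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(m$faces[2, ], c(1L, 3L, 4L), ignore_attr = TRUE)

  writeLines(c("v 0 0", "f 1 2 3"), path)
  expect_error(read_obj(path), "malformed")
  writeLines(c("v 0 0 0", "f 1 2"), path)
  expect_error(read_obj(path), "malformed|face")
})

test_that("face_mesh validates indices and degenerate triangles", {
  v <- diag(3)
  expect_error(face_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(face_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_error(face_mesh(v[, 1:2], rbind(c(1, 2, 3))), "N x 3")
})

test_that("extract_boundary errors on closed meshes and returns the full rim of a disk", {
  expect_error(extract_boundary(octahedron()), "no boundary")
  K <- 9
  b <- extract_boundary(disk_fan(K))
  expect_true(b$closed)
  expect_equal(nrow(b$points), K)
  # boundary length matches the brute-force edge-incidence count
  expect_equal(nrow(b$points), count_boundary_edges(disk_fan(K)))
})

test_that("extract_boundary matches the edge-incidence oracle on a defective face", {
  tpl <- tiny_template()
  def <- simulate_defect(tpl$mesh, tpl, source_id = "tpl")
  b <- def$defect_curve
  expect_equal(nrow(b$points), count_boundary_edges(def$mesh))
  # two loops (sheet with a hole) is an error unless the longest is requested
  sheet <- grid_sheet(8)
  hole <- submesh(sheet, setdiff(seq_len(64), c(28, 29)))
  expect_error(extract_boundary(hole), "2 boundary loops")
  expect_s3_class(extract_boundary(hole, select_longest = TRUE),
                  "boundary_curve")
})

test_that("select_region partitions vertices and recovers the template nose set", {
  tpl <- tiny_template()
  def <- simulate_defect(tpl$mesh, tpl, source_id = "tpl")
  mask <- select_region(tpl$mesh, def$defect_curve)
  expect_identical(unname(which(mask)), unname(which(tpl$nose_mask)))
  path <- attr(mask, "path_vertices")
  n <- nrow(tpl$mesh$vertices)
  # partition: region, complement, path are disjoint and exhaustive
  comp <- !mask & !(seq_len(n) %in% path)
  expect_equal(sum(mask) + sum(comp) + length(path), n)
  expect_equal(sum(mask & comp), 0)
  # swapping the anchor into the nose yields the complementary region
  inner <- which(tpl$nose_mask)[1]
  mask2 <- select_region(tpl$mesh, def$defect_curve, anchor = inner)
  expect_identical(unname(which(mask2)), unname(which(comp)))
})

test_that("select_region extracts a single vertex star", {
  sheet <- grid_sheet(7)
  center <- 25L  # (4,4) interior vertex
  nbr_edges <- nasorecon:::mesh_edges(sheet)
  nbrs <- sort(unique(c(nbr_edges[nbr_edges[, 1] == center, 2],
                        nbr_edges[nbr_edges[, 2] == center, 1])))
  curve <- boundary_curve(sheet$vertices[nbrs, ][order(
    atan2(sheet$vertices[nbrs, 2] - sheet$vertices[center, 2],
          sheet$vertices[nbrs, 1] - sheet$vertices[center, 1])), ],
    closed = TRUE)
  mask <- select_region(sheet, curve)
  expect_identical(which(mask), center)
})

test_that("submesh reindexes and keeps only fully selected faces", {
  sheet <- grid_sheet(5)
  mask <- rep(FALSE, 25)
  mask[c(1, 2, 6, 7)] <- TRUE   # one quad corner = 2 triangles
  sm <- submesh(sheet, mask)
  expect_equal(nrow(sm$vertices), 4L)
  expect_equal(nrow(sm$faces), 2L)
  expect_equal(attr(sm, "orig_index"), c(1L, 2L, 6L, 7L))
})
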