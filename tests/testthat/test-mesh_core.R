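test_that("single unit tet parses from INP with the closed-form volume", {
  path <- withr::local_tempfile(fileext = ".inp")
  inp_single_tet(path)
  m <- read_mesh(path)
  expect_s3_class(m, "tet_mesh")
  expect_equal(nrow(m$elems), 1L)
  expect_equal(tet_volumes(m), 1 / 6, tolerance = 1e-15)
  expect_equal(m$region, "cortical")
})

test_that("INP reader rejects bad records and skips unknown keywords", {
  path <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("*NODE", "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0",
               "*ELEMENT, TYPE=C3D4, ELSET=cortical",
               "1, 1, 2, 3, 99"), path)
  expect_error(read_mesh(path), "element 1.*node id 99")

  writeLines(c("*NODE", "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0",
               "4, 0, 0, 1",
               "*SURFACE, NAME=foo", "whatever",
               "*ELEMENT, TYPE=C3D4, ELSET=cortical",
               "1, 1, 2, 3, 4"), path)
  expect_warning(m <- read_mesh(path), "skipping unsupported INP keyword")
  expect_equal(nrow(m$elems), 1L)

  # duplicate element ids are a hard error
  writeLines(c("*NODE", "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0",
               "4, 0, 0, 1", "5, 1, 1, 1",
               "*ELEMENT, TYPE=C3D4, ELSET=cortical",
               "7, 1, 2, 3, 4", "7, 2, 3, 4, 5"), path)
  expect_error(read_mesh(path), "duplicate element id")
})

test_that("mesh constructor enforces the invariants", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(tet_mesh(nodes, matrix(c(1, 2, 3, 3), 1), "cortical"),
               "repeat a node")
  expect_error(tet_mesh(nodes, matrix(c(1, 2, 3, 9), 1), "cortical"),
               "nonexistent node")
  expect_error(tet_mesh(nodes, matrix(1:4, 1), "bone"), "unknown region")
  # degenerate (coplanar) tet
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(tet_mesh(flat, matrix(1:4, 1), "cortical"), "degenerate")
  # inverted ordering is repaired
  expect_message(m <- tet_mesh(nodes, matrix(c(1, 3, 2, 4), 1), "cortical"),
                 "repaired")
  expect_gt(tet_volumes(m), 0)
  expect_error(tet_mesh(nodes, matrix(1:4, 1), "cortical",
                        node_sets = list(bad = 99L)), "nonexistent ids")
})

test_that("INP and JSON round trips are the identity", {
  ph <- quick_phantom()
  for (fmt in c("inp", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(ph, path, fmt)
    back <- read_mesh(path, fmt)
    expect_equal(back$nodes, ph$nodes, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(back$elems, ph$elems, ignore_attr = TRUE)
    expect_identical(back$region, ph$region)
    expect_identical(lapply(back$node_sets, as.integer), ph$node_sets)
    expect_identical(lapply(back$elem_sets, as.integer), ph$elem_sets)
  }
})

test_that("surface extraction matches combinatorics and brute force", {
  # single tet: all 4 faces on the boundary
  m1 <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 matrix(1:4, 1), "cortical")
  s1 <- extract_surface(m1)
  expect_equal(nrow(s1$faces), 4L)
  expect_equal(sqrt(rowSums(s1$normals^2)), rep(1, 4), tolerance = 1e-12)
  # normals point away from the centroid
  ctr <- colMeans(m1$nodes)
  expect_true(all(rowSums(s1$normals * (s1$centroids -
                                          matrix(ctr, 4, 3, TRUE))) > 0))

  # two tets sharing a face: 6 boundary faces, shared face absent
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  m2 <- suppressMessages(
    tet_mesh(nodes, rbind(1:4, c(2, 3, 4, 5)), rep("cortical", 2)))
  s2 <- extract_surface(m2)
  expect_equal(nrow(s2$faces), 6L)
  expect_equal(sort(unique(s2$owner)), 1:2)

  # phantom: boundary count equals the face-multiplicity oracle
  ph <- quick_phantom()
  expect_equal(nrow(extract_surface(ph)$faces),
               oracle_boundary_face_count(ph))
})

test_that("VTK export round-trips geometry and cell data", {
  ph <- quick_phantom()
  path <- withr::local_tempfile(fileext = ".vtk")
  ids <- as.numeric(seq_len(nrow(ph$elems)))
  write_vtk(ph, path, cell_data = list(const = rep(1, nrow(ph$elems)),
                                       elem_id = ids))
  back <- jawstrain:::.read_vtk(path)
  expect_equal(back$nodes, ph$nodes, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$elems, ph$elems, ignore_attr = TRUE)
  expect_identical(names(back$cell_data), c("const", "elem_id"))
  expect_equal(back$cell_data$const, rep(1, nrow(ph$elems)))
  expect_equal(back$cell_data$elem_id, ids)

  # geometry-only file
  write_vtk(ph, path)
  expect_length(jawstrain:::.read_vtk(path)$cell_data, 0L)

  # mismatched field length
  expect_error(write_vtk(ph, path, cell_data = list(x = 1:3)),
               "length")
})
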