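test_that("OBJ round trip preserves a tetrahedron exactly", {
  m <- mesh_tetrahedron()
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(m2$faces, m$faces)
})

test_that("PLY round trips in ascii and binary to 1e-5 mm", {
  m <- mesh_icosphere(2, radius = 13.7)
  for (bin in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_mesh(m, path, binary = bin)
    m2 <- read_mesh(path)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-5)
    expect_identical(m2$faces, m$faces)
  }
})

test_that("PLY file with vertices but no faces is an empty-mesh error", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property double x", "property double y",
               "property double z", "element face 0",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 1 1"), path)
  expect_error(read_mesh(path), "empty mesh")
})

test_that("binary STL of a cube deduplicates 36 corners to 8 vertices", {
  cube <- mesh_cube(2, center = c(1, -3, 0.5))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path)
  m2 <- read_mesh(path)
  expect_identical(nrow(m2$vertices), 8L)
  expect_identical(nrow(m2$faces), 12L)
  # coordinates survive the float32 round trip well under 1e-5 mm
  o <- m2$vertices[order(m2$vertices[, 1], m2$vertices[, 2],
                         m2$vertices[, 3]), ]
  e <- cube$vertices[order(cube$vertices[, 1], cube$vertices[, 2],
                           cube$vertices[, 3]), ]
  expect_lt(max(abs(o - e)), 1e-5)
})

test_that("STL export of a non-watertight surface warns but succeeds", {
  open_surface <- mesh_plane(5, 5)
  path <- withr::local_tempfile(fileext = ".stl")
  expect_warning(write_mesh(open_surface, path), "non-watertight")
  expect_true(file.exists(path))
})

test_that("watertightness is preserved through STL export and re-import", {
  closed <- mesh_icosphere(1, radius = 4)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(closed, path)
  expect_identical(validate_mesh(read_mesh(path))$is_watertight,
                   validate_mesh(closed)$is_watertight)
})

test_that("unreadable files and unknown formats raise errors", {
  expect_error(read_mesh("no/such/file.obj"), "not found")
  expect_error(read_mesh(withr::local_tempfile(fileext = ".xyz")))
})
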