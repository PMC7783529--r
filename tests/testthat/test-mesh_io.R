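test_that("OBJ reader handles minimal cubes, quads and negative indices", {
  f <- withr::local_tempfile(fileext = ".obj")
  # minimal cube: 8 vertices, 12 triangles
  write_mesh(unit_cube(), f)
  m <- read_mesh(f)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  expect_identical(m$name, tools::file_path_sans_ext(basename(f)))

  # a quad face fan-triangulates into 2 triangles, order preserved
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), f)
  q <- read_mesh(f)
  expect_identical(q$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))

  # negative indices resolve relative to the vertices defined so far
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f -3 -2 -1"), f)
  n <- read_mesh(f)
  expect_identical(n$faces, rbind(c(1L, 2L, 3L)))

  # vt/vn/usemtl records and face index suffixes are ignored
  writeLines(c("usemtl none", "v 0 0 0", "v 1 0 0", "v 0 1 0",
               "vn 0 0 1", "vt 0 0", "f 1/1/1 2/1/1 3/1/1"), f)
  s <- read_mesh(f)
  expect_identical(s$faces, rbind(c(1L, 2L, 3L)))

  # errors name the offending line
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), f)
  expect_error(read_mesh(f), "line 4")
  writeLines(c("v 0 0 x", "f 1 1 1"), f)
  expect_error(read_mesh(f), "line 1")
  writeLines(c("v 0 0 0"), f)
  expect_error(read_mesh(f), "empty mesh")
})

test_that("write/read round-trips reproduce vertices and faces in all formats", {
  set.seed(7)
  m <- random_hull_mesh(16)
  m$name <- "roundtrip"
  for (spec in list(list(ext = ".obj", binary = FALSE),
                    list(ext = ".ply", binary = FALSE),
                    list(ext = ".ply", binary = TRUE))) {
    f <- withr::local_tempfile(fileext = spec$ext)
    write_mesh(m, f, binary = spec$binary)
    r <- read_mesh(f, name = "roundtrip")
    expect_equal(r$vertices, m$vertices, tolerance = 0,
                 label = paste("vertices", spec$ext, spec$binary))
    expect_identical(r$faces, m$faces)
  }
  # STL loses vertex indexing: compare welded geometry and volume instead
  for (binary in c(FALSE, TRUE)) {
    # binary STL stores float32: use float32-representable coordinates
    mm <- if (binary) make_box(c(0.25, 8, 1.5), name = "stl") else m
    f <- withr::local_tempfile(fileext = ".stl")
    write_mesh(mm, f, binary = binary)
    r <- read_mesh(f)
    expect_equal(nrow(r$faces), nrow(mm$faces))
    expect_identical(signed_volume(r), signed_volume(mm))
    expect_true(validate_mesh(r)$watertight)
  }
})

test_that("PLY binary little-endian crafted independently matches the OBJ cube", {
  # bytes written by hand here, not by the package writer
  v <- unit_cube()$vertices
  fc <- unit_cube()$faces
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 8",
               "property float x", "property float y", "property float z",
               "element face 12",
               "property list uchar uint vertex_indices",
               "end_header"), con)
  writeBin(as.vector(t(v)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(fc))) {
    writeBin(as.raw(3L), con)
    writeBin(fc[i, ] - 1L, con, size = 4L, endian = "little")
  }
  close(con)
  m <- read_mesh(f)
  expect_equal(m$vertices, v, tolerance = 0)
  expect_identical(m$faces, fc)
})

test_that("read_collection walks tissue subdirectories deterministically", {
  root <- withr::local_tempdir()
  for (t in c("intestine", "neurons")) {
    dir.create(file.path(root, t))
    for (i in 1:3)
      write_mesh(make_box(i, name = sprintf("%s%d", substr(t, 1, 3), i)),
                 file.path(root, t, sprintf("%s%d.obj", substr(t, 1, 3), i)))
  }
  ms <- read_collection(root)
  expect_length(ms, 6L)
  expect_identical(vapply(ms, `[[`, "", "collection"),
                   rep(c("intestine", "neurons"), each = 3L))
  expect_identical(vapply(ms, `[[`, "", "name"),
                   c("int1", "int2", "int3", "neu1", "neu2", "neu3"))
  # same names again -> identical order (stability)
  expect_identical(vapply(read_collection(root), `[[`, "", "name"),
                   vapply(ms, `[[`, "", "name"))

  # duplicate cell name across collections
  write_mesh(make_box(1, name = "int1"), file.path(root, "neurons", "int1.obj"))
  expect_error(read_collection(root), "duplicate cell names.*int1")

  expect_error(read_collection(file.path(root, "missing")), "not found")
  empty <- withr::local_tempdir()
  expect_error(read_collection(empty), "no mesh files")
})

test_that("bake_transform applies, composes, and preserves orientation under mirrors", {
  m <- unit_tetra()
  expect_equal(bake_transform(m, affine_transform()), m)

  s2 <- transform_scale(2)
  expect_identical(signed_volume(bake_transform(m, s2)), 8 * signed_volume(m))

  tr <- transform_translate(c(3, -1, 2))
  both <- bake_transform(bake_transform(m, tr), s2)
  composed <- bake_transform(m, transform_compose(s2, tr))
  expect_equal(both$vertices, composed$vertices, tolerance = 1e-15)
  expect_identical(both$faces, composed$faces)

  # mirror: winding flipped so the signed volume keeps its sign
  mir <- affine_transform(diag(c(-1, 1, 1)))
  mm <- bake_transform(m, mir)
  expect_identical(mm$faces, flip_faces(m)$faces)
  expect_identical(signed_volume(mm), signed_volume(m))

  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
})
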