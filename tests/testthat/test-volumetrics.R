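test_that("validate_mesh counts boundary edges, windings and duplicates", {
  cube <- unit_cube()
  r <- validate_mesh(cube)
  expect_true(r$watertight)
  expect_true(r$orientation_consistent)
  expect_identical(r$boundary_edge_count, 0L)
  expect_identical(r$non_manifold_edge_count, 0L)
  expect_identical(r$duplicate_vertex_count, 0L)

  # one face removed -> its 3 edges become boundary edges
  holed <- perturb(cube, "puncture", n_faces = 1L, seed = 3)
  rh <- validate_mesh(holed)
  expect_false(rh$watertight)
  expect_identical(rh$boundary_edge_count, 3L)
  expect_true(is.na(rh$orientation_consistent))

  # one flipped face breaks orientation consistency but not watertightness
  rf <- validate_mesh(perturb(cube, "flip_one"))
  expect_true(rf$watertight)
  expect_false(rf$orientation_consistent)

  # duplicated vertex (unreferenced) is counted, never merged
  dup <- cube
  dup$vertices <- rbind(dup$vertices, dup$vertices[1L, ])
  expect_identical(validate_mesh(dup)$duplicate_vertex_count, 1L)
})

test_that("repair_orientation restores consistent outward windings", {
  cube <- unit_cube()
  v <- signed_volume(cube)

  inward <- flip_faces(cube)
  fixed <- repair_orientation(inward)
  expect_identical(signed_volume(fixed), v)

  # idempotent on an already-consistent mesh
  expect_identical(repair_orientation(cube)$faces, cube$faces)

  # a single flipped face is restored; volume equals the clean cube's
  one <- perturb(cube, "flip_one")
  expect_identical(signed_volume(repair_orientation(one)), v)

  holed <- perturb(cube, "puncture", n_faces = 1L)
  expect_error(repair_orientation(holed), "not watertight")
})

test_that("signed_volume matches closed forms exactly", {
  expect_identical(signed_volume(make_box(c(100, 100, 100))), 1e6)
  expect_identical(signed_volume(unit_tetra()), 1 / 6)
  # inscribed icosphere is strictly below the smooth sphere
  expect_lt(signed_volume(make_icosphere(1, 4)), 4 * pi / 3)
})

test_that("signed_volume properties: translation invariance, antisymmetry, scaling, additivity", {
  set.seed(11)
  for (i in 1:10) {
    scale <- 10^sample(-1:2, 1)
    m <- random_hull_mesh(sample(8:25, 1), scale = scale)
    v <- signed_volume(m)
    # translation invariance (watertight mesh); offset at mesh scale — a
    # 1e-9 relative bound cannot survive arbitrarily distant origins in
    # double precision
    off <- stats::rnorm(3, sd = 5 * scale)
    expect_equal(signed_volume(bake_transform(m, transform_translate(off))), v,
                 tolerance = 1e-9)
    # antisymmetry is exact
    expect_identical(signed_volume(flip_faces(m)), -v)
    # scaling law s^3
    s <- stats::runif(1, 0.5, 3)
    expect_equal(signed_volume(bake_transform(m, transform_scale(s))),
                 s^3 * v, tolerance = 1e-12)
    # dual route: centroid-anchored decomposition agrees with the
    # origin-anchored divergence sum
    expect_equal(convex_volume_oracle(m), v, tolerance = 1e-9)
  }

  # additivity: two boxes sharing a planar cap sum to the enclosing box
  whole <- make_box(c(2, 3, 5))
  lower <- make_box(c(2, 3, 2))
  upper <- bake_transform(make_box(c(2, 3, 3)), transform_translate(c(0, 0, 2)))
  expect_equal(signed_volume(lower) + signed_volume(upper),
               signed_volume(whole), tolerance = 1e-9)
})

test_that("icosphere volume converges monotonically to 4*pi*r^3/3", {
  vols <- vapply(0:4, function(s) signed_volume(make_icosphere(1, s)), 0)
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 * pi / 3))
  expect_equal(vols[5L], 4 * pi / 3, tolerance = 3e-3)
})

test_that("calibrate turns a known reference into a volumetric factor", {
  expect_identical(calibrate(make_box(c(100, 100, 100)), 1e6)$volume_factor, 1)
  expect_identical(calibrate(make_box(c(1, 1, 1)), 1e6)$volume_factor, 1e6)

  # a smooth reference of known analytic volume recovers unity within the
  # polyhedral discretisation deficit
  cal <- calibrate(make_icosphere(1, 4), known_volume = 4 * pi / 3)
  expect_gt(cal$volume_factor, 1)
  expect_equal(cal$volume_factor, 1, tolerance = 3e-3)

  expect_error(calibrate(make_box(1), known_volume = 0), "positive")
  expect_error(calibrate(perturb(unit_cube(), "puncture"), 1e6),
               "not watertight")
})

test_that("measure_cells applies the defective-mesh policy", {
  cal <- calibrate(make_box(c(1, 1, 1)), 1e6)  # factor 1e6
  clean <- make_box(2, name = "clean"); clean$collection <- "t"
  holed <- perturb(make_box(2, name = "holed"), "puncture"); holed$collection <- "t"
  oneflip <- perturb(make_box(2, name = "oneflip"), "flip_one")
  oneflip$collection <- "t"
  inverted <- flip_faces(make_box(2, name = "inv")); inverted$collection <- "t"

  m <- measure_cells(list(clean, holed), cal, policy = "exclude")
  expect_identical(m$excluded, c(FALSE, TRUE))
  expect_identical(m$calibrated_volume_um3[1L], 8e6)
  expect_true(is.na(m$raw_volume[2L]))

  # a fully inward mesh is consistently wound: the absolute value convention
  # measures it correctly under either policy
  mi <- measure_cells(list(clean, inverted), cal, policy = "exclude")
  expect_false(any(mi$excluded))
  expect_identical(mi$calibrated_volume_um3[2L], mi$calibrated_volume_um3[1L])

  # repair restores a single-flipped-face twin to the clean value
  mr <- measure_cells(list(clean, oneflip), cal, policy = "repair")
  expect_false(any(mr$excluded))
  expect_identical(mr$calibrated_volume_um3[2L], mr$calibrated_volume_um3[1L])

  # under exclude, inconsistent winding is defective, not silently fixed
  me <- measure_cells(list(clean, oneflip), cal, policy = "exclude")
  expect_identical(me$excluded, c(FALSE, TRUE))

  expect_error(measure_cells(list(holed), cal, policy = "exclude"),
               "all 1 meshes are defective")
  expect_warning(measure_cells(list(clean, holed), cal, policy = "repair"),
                 "cannot be repaired")
})
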