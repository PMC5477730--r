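# Voxel-domain structure construction: rasterization, mask/mesh
# conversion, isotropic expansion, cropping, boolean algebra.

test_that("rasterizing a unit cube on a 0.1 mm grid recovers its volume", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  m <- rasterize(cube, origin = c(0.05, 0.05, 0.05),
                 spacing = c(0.1, 0.1, 0.1), shape = c(10L, 10L, 10L))
  expect_lt(abs(mask_volume(m) - 1) / 1, 0.03)

  far <- rasterize(cube, origin = c(50, 50, 50), spacing = c(1, 1, 1),
                   shape = c(5L, 5L, 5L))
  expect_equal(sum(far$occupancy), 0L)

  open_mesh <- cube
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(rasterize(open_mesh, like = m), "closed")
})

test_that("mask_to_mesh emits a closed mesh whose volume equals the voxel count", {
  one <- structure_mask(c(0, 0, 0), c(1, 1, 1),
                        array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)),
                              c(3, 3, 3)))
  m1 <- mask_to_mesh(one)
  expect_equal(mesh_open_edges(m1), 0L)
  expect_equal(mesh_volume(m1), 1.0)

  ball <- ball_mask(10, half_extent = 12)
  mb <- mask_to_mesh(ball)
  expect_equal(mesh_open_edges(mb), 0L)
  expect_equal(mesh_volume(mb), mask_volume(ball))
  expect_lt(abs(mesh_volume(mb) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.02)

  # two isolated voxels: two closed components, 8 corners each
  two <- array(FALSE, c(4, 4, 4)); two[1, 1, 1] <- TRUE; two[4, 4, 4] <- TRUE
  m2 <- mask_to_mesh(structure_mask(c(0, 0, 0), c(1, 1, 1), two))
  expect_equal(nrow(m2$vertices), 16L)
  expect_equal(mesh_volume(m2), 2.0)

  empty <- structure_mask(c(0, 0, 0), c(1, 1, 1), array(FALSE, c(2, 2, 2)))
  expect_error(mask_to_mesh(empty), "empty")
})

test_that("rasterize and mask_to_mesh round-trip preserves volume", {
  sph <- mesh_icosphere(8, subdivisions = 3)
  m <- rasterize(sph, origin = c(-10.5, -10.5, -10.5), spacing = c(1, 1, 1),
                 shape = c(22L, 22L, 22L))
  back <- mask_to_mesh(m)
  expect_lt(abs(mesh_volume(back) - mesh_volume(sph)) / mesh_volume(sph),
            0.05)
})

test_that("isotropic expansion matches the analytic ball and the exhaustive oracle", {
  ball <- ball_mask(10, half_extent = 21)
  expect_identical(expand_isotropic(ball, 0)$occupancy, ball$occupancy)

  grown <- expand_isotropic(ball, 8)
  v_true <- 4 / 3 * pi * 18^3
  # expanding a digitized ball loses ~a quarter voxel of radius in lattice
  # directions with no centre close to the surface, so the margin-expanded
  # volume sits a few percent below the continuous Minkowski sum
  expect_lt(abs(mask_volume(grown) - v_true) / v_true, 0.05)
  expect_true(all(!ball$occupancy | grown$occupancy))

  # anisotropic 20^3 brute force
  set.seed(7)
  m <- random_mask(shape = c(20, 20, 20), spacing = c(1, 1.3, 2.1), p = 0.01)
  for (margin in c(2.5, 4.0)) {
    expect_identical(expand_isotropic(m, margin)$occupancy,
                     oracle_expand(m, margin)$occupancy)
  }

  expect_error(expand_isotropic(ball, -1), "margin")
})

test_that("expansion is monotone in both the set and the margin", {
  set.seed(11)
  a <- random_mask()
  b <- a
  extra <- which(!b$occupancy)
  b$occupancy[extra[seq_len(20)]] <- TRUE   # a strict superset
  ea <- expand_isotropic(a, 3)
  eb <- expand_isotropic(b, 3)
  expect_true(all(!ea$occupancy | eb$occupancy))

  e1 <- expand_isotropic(a, 2)
  e2 <- expand_isotropic(a, 5)
  expect_true(all(!e1$occupancy | e2$occupancy))
})

test_that("two-step expansion approximates one-step within a voxel diagonal", {
  set.seed(13)
  a <- random_mask(shape = c(14, 14, 10), p = 0.03)
  two <- expand_isotropic(expand_isotropic(a, 2.4), 3.1)
  one <- expand_isotropic(a, 5.5)
  diag_ <- sqrt(sum(a$spacing^2))
  two_relaxed <- expand_isotropic(two, diag_)
  expect_true(all(!one$occupancy | two_relaxed$occupancy))
})

test_that("boolean mask algebra satisfies inclusion-exclusion exactly", {
  set.seed(21)
  a <- random_mask(p = 0.2)
  b <- random_mask(p = 0.2)
  expect_equal(mask_volume(mask_union(a, b)) + mask_volume(mask_intersect(a, b)),
               mask_volume(a) + mask_volume(b))
  expect_equal(mask_volume(mask_subtract(a, b)),
               mask_volume(a) - mask_volume(mask_intersect(a, b)))
  expect_equal(sum(mask_subtract(a, a)$occupancy), 0L)
  emp <- structure_mask(a$origin, a$spacing, array(FALSE, a$shape))
  expect_identical(mask_subtract(a, emp)$occupancy, a$occupancy)

  shifted <- structure_mask(a$origin + 1, a$spacing, a$occupancy)
  expect_error(mask_subtract(a, shifted), "grid")
})

test_that("concentric ball subtraction yields the analytic shell volume", {
  big <- ball_mask(18, half_extent = 21)
  small <- ball_mask(10, half_extent = 21)
  shell <- mask_subtract(big, small)
  v_true <- 4 / 3 * pi * (18^3 - 10^3)
  expect_lt(abs(mask_volume(shell) - v_true) / v_true, 0.03)
})

test_that("CTV construction expands then crops and never enters a barrier", {
  set.seed(31)
  gtv <- ball_mask(6, half_extent = 16)
  emp <- structure_mask(gtv$origin, gtv$spacing, array(FALSE, gtv$shape))
  no_barriers <- barrier_set(emp, emp, emp)
  expect_identical(build_ctv(gtv, 0, no_barriers)$occupancy, gtv$occupancy)

  air_occ <- array(FALSE, gtv$shape)
  air_occ[1:16, , ] <- TRUE                        # half-space barrier
  barriers <- barrier_set(structure_mask(gtv$origin, gtv$spacing, air_occ),
                          emp, emp)
  ctv <- build_ctv(gtv, 5, barriers)
  expect_false(any(ctv$occupancy & air_occ))
  expect_identical(ctv$occupancy,
                   crop_to_barriers(expand_isotropic(gtv, 5), barriers)$occupancy)

  all_occ <- structure_mask(gtv$origin, gtv$spacing, array(TRUE, gtv$shape))
  expect_equal(sum(build_ctv(gtv, 5, barrier_set(all_occ, emp, emp))$occupancy), 0L)

  # a larger GTV yields a superset CTV under identical cropping
  gtv_l <- ball_mask(7, half_extent = 16)
  ctv_l <- build_ctv(gtv_l, 5, barriers)
  expect_true(all(!ctv$occupancy | ctv_l$occupancy))
})

test_that("window presets validate their HU bounds", {
  w <- window_preset(-1000, 0)
  expect_equal(c(w$hu_min, w$hu_max), c(-1000, 0))
  expect_error(window_preset(0, -1000), "hu_min")
})
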