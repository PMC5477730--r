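# Mesh volumes, surfaces and 3D Hausdorff distances against closed forms
# and brute-force oracles.

test_that("volume and surface are exact for polyhedra and converge for spheres", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  expect_equal(mesh_volume(cube), 1.0)
  expect_equal(mesh_surface_area(cube), 6.0)

  sph <- mesh_icosphere(10, subdivisions = 4)
  expect_lt(abs(mesh_volume(sph) - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3),
            0.005)
  expect_lt(abs(mesh_surface_area(sph) - 4 * pi * 100) / (4 * pi * 100),
            0.005)

  # a single triangle has area 1/2 and, doubled back on itself, encloses
  # nothing (all vertices coplanar)
  tri <- triangular_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                         rbind(c(1, 2, 3)), normalize = FALSE)
  expect_equal(mesh_surface_area(tri), 0.5)
  flat <- triangular_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                          rbind(c(1, 2, 3), c(1, 3, 2)), normalize = FALSE)
  expect_equal(mesh_open_edges(flat), 0L)
  expect_equal(mesh_volume(flat), 0.0)
})

test_that("open meshes are rejected with the open-edge count", {
  sph <- mesh_icosphere(5, subdivisions = 1)
  broken <- sph
  broken$faces <- broken$faces[-1, ]
  expect_equal(mesh_open_edges(broken), 3L)
  expect_error(mesh_volume(broken), "3 open edge")
})

test_that("orientation normalization repairs scrambled windings", {
  sph <- mesh_icosphere(8, subdivisions = 2)
  v_true <- mesh_volume(sph)
  scrambled <- sph$faces
  set.seed(42)
  flip <- sample(nrow(scrambled), nrow(scrambled) %/% 2)
  scrambled[flip, ] <- scrambled[flip, c(1, 3, 2)]
  fixed <- triangular_mesh(sph$vertices, scrambled, normalize = TRUE)
  expect_equal(mesh_volume(fixed), v_true, tolerance = 1e-12)
})

test_that("volume is rigid-motion invariant and scales as s^3, surface as s^2", {
  m <- mesh_icosphere(6, subdivisions = 2)
  v0 <- mesh_volume(m); a0 <- mesh_surface_area(m)

  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mt <- m
  mt$vertices <- sweep(m$vertices %*% t(rot), 2, c(5, -3, 11), "+")
  expect_equal(mesh_volume(mt), v0, tolerance = 1e-9)
  expect_equal(mesh_surface_area(mt), a0, tolerance = 1e-9)

  for (s in c(0.5, 2.3)) {
    ms <- m
    ms$vertices <- m$vertices * s
    expect_equal(mesh_volume(ms), v0 * s^3, tolerance = 1e-9)
    expect_equal(mesh_surface_area(ms), a0 * s^2, tolerance = 1e-9)
  }
})

test_that("3D Hausdorff distance matches analytic cases", {
  s10 <- mesh_icosphere(10, subdivisions = 3)
  expect_equal(hausdorff_3d(s10, s10), 0.0)

  s15 <- mesh_icosphere(15, subdivisions = 3)
  expect_equal(hausdorff_3d(s10, s15), 5.0, tolerance = 0.02)

  # HD of a convex body and its translate equals the translation norm
  moved <- mesh_icosphere(10, center = c(3, 0, 0), subdivisions = 3)
  expect_equal(hausdorff_3d(s10, moved), 3.0, tolerance = 0.02)

  expect_error(
    hausdorff_3d(s10, triangular_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))),
    "empty")
})

test_that("Hausdorff distance is symmetric and obeys the triangle bound", {
  a <- mesh_icosphere(10, subdivisions = 2)
  b <- mesh_icosphere(12, center = c(2, 1, 0), subdivisions = 2)
  c_ <- mesh_box(c(-4, -4, -4), c(4, 4, 4))
  expect_identical(hausdorff_3d(a, b), hausdorff_3d(b, a))
  expect_lte(hausdorff_3d(a, c_),
             hausdorff_3d(a, b) + hausdorff_3d(b, c_) + 1e-9)
})

test_that("accelerated surface distances agree with the brute-force oracle", {
  # meshes small enough to scan every point-triangle pair
  a <- mesh_icosphere(10, subdivisions = 1)          # 42 vertices
  b <- mesh_icosphere(12, center = c(1.5, -0.8, 0.4), subdivisions = 1)
  expect_lte(nrow(a$vertices), 200)
  pa <- sample_mesh_points(a, density = 0.05)
  pb <- sample_mesh_points(b, density = 0.05)
  hd_oracle <- max(oracle_directed_hd(pa, b), oracle_directed_hd(pb, a))
  hd_pkg <- hausdorff_3d(a, b, sampling_density = 0.05)
  expect_equal(hd_pkg, hd_oracle, tolerance = 1e-9)
})

test_that("paired-structure reports capture the volume difference fraction", {
  a <- mesh_icosphere(10, subdivisions = 3)
  r_same <- compare_pair(a, a)
  expect_equal(r_same$volume_difference_fraction, 0.0)
  expect_equal(r_same$hd3d_mm, 0.0)
  expect_equal(r_same$hd2d_mm, 0.0)

  b <- mesh_icosphere(10.29, subdivisions = 3)
  r <- compare_pair(a, b)
  expect_equal(r$volume_difference_fraction, (10.29 / 10)^3 - 1,
               tolerance = 0.005)
  expect_lt(abs(r$hd3d_mm - 0.29), 0.05)   # chord-height sampling slack
  expect_equal(unname(r$volume_cm3["S"]), 4 / 3 * pi * 10^3 / 1000,
               tolerance = 0.01)
})

test_that("cohort summaries report median, sd and range per metric", {
  mk_report <- function(hd) {
    structure(list(id = NULL, volume_cm3 = c(S = 1, L = 1.1),
                   surface_cm2 = c(S = 5, L = 5.2), hd3d_mm = hd,
                   hd2d_mm = hd / 2, hd2d_per_slice = c(`0` = hd / 2),
                   unmatched_slices = 0L,
                   volume_difference_fraction = 0.1),
              class = "geometry_report")
  }
  reports <- lapply(c(1, 2, 3), mk_report)
  s <- summarize_cohort(reports)
  row <- s[s$metric == "hd3d_mm", ]
  expect_equal(row$median, 2)
  expect_equal(row$sd, 1)          # sample SD of {1,2,3}
  expect_equal(c(row$min, row$max), c(1, 3))

  one <- summarize_cohort(reports[1])
  expect_equal(one[one$metric == "hd3d_mm", "median"], 1)
  expect_equal(one[one$metric == "hd3d_mm", "sd"], 0)

  expect_error(summarize_cohort(list()), "empty")
})
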