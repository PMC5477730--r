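# The seeded synthetic phantom: geometry invariants, dose model
# properties, parameter recovery and determinism.

bundle_default <- NULL
get_default_bundle <- function() {
  if (is.null(bundle_default)) {
    bundle_default <<- generate_phantom(phantom_spec())
  }
  bundle_default
}

test_that("phantom structure invariants hold on the default spec", {
  b <- get_default_bundle()
  expect_true(all(!b$gtv_s$occupancy | b$gtv_l$occupancy))   # S inside L
  expect_false(any(b$gtv_l$occupancy & b$barriers$air$occupancy))
  barrier_any <- b$barriers$air$occupancy | b$barriers$bone$occupancy |
    b$barriers$anatomical$occupancy
  expect_false(any(b$ctv_l$occupancy & barrier_any))
  expect_false(any(b$ctv_s$occupancy & barrier_any))
  expect_true(all(!b$ctv_s$occupancy | b$ctv_l$occupancy))
  # the air barrier is exactly the lung-window voxels inside the body
  lung <- window_mask(b$hu_image, b$gtv_s$origin, b$gtv_s$spacing,
                      window_preset(-1000, 0))
  body <- structure_mask(b$gtv_s$origin, b$gtv_s$spacing,
                         !b$barriers$anatomical$occupancy)
  expect_identical(b$barriers$air$occupancy,
                   mask_intersect(lung, body)$occupancy)
  # HU bands: cavity air below -900, tissue in [0, 80], bone at 700+
  expect_true(all(b$hu_image[b$barriers$air$occupancy] <= -900))
  expect_true(all(b$hu_image[b$gtv_s$occupancy] >= 0 &
                  b$hu_image[b$gtv_s$occupancy] <= 80))
  expect_true(all(b$hu_image[b$barriers$bone$occupancy] >= 700))
})

test_that("the generated volume increase matches the configured fraction", {
  b <- get_default_bundle()
  vs <- mask_volume(b$gtv_s); vl <- mask_volume(b$gtv_l)
  expect_lt(abs((vl - vs) / vs - 0.09), 0.02)
  # voxel volumes recover the analytic ground truth within 3%
  gt <- b$ground_truth
  expect_lt(abs(vs - gt$volume_s_mm3) / gt$volume_s_mm3, 0.03)
  expect_lt(abs(vl - gt$volume_l_mm3) / gt$volume_l_mm3, 0.03)
})

test_that("the full mesh pipeline recovers the configured iceberg depth", {
  b <- get_default_bundle()
  hd <- hausdorff_3d(mask_to_mesh(b$gtv_s), mask_to_mesh(b$gtv_l))
  voxel_diag <- sqrt(sum(b$gtv_s$spacing^2))
  expect_lt(abs(hd - b$ground_truth$iceberg_depth_mm), voxel_diag)
})

test_that("zero iceberg depth gives identical paired structures", {
  spec0 <- phantom_spec(iceberg_depth = 0, shape = c(81L, 81L, 25L),
                        origin = c(-40, -40, -24), outer_radius = 20,
                        height = 14)
  b0 <- generate_phantom(spec0)
  expect_identical(b0$gtv_s$occupancy, b0$gtv_l$occupancy)
  expect_equal(hausdorff_3d(mask_to_mesh(b0$gtv_s), mask_to_mesh(b0$gtv_l)),
               0)
})

test_that("infeasible iceberg depths and fractions are rejected", {
  expect_error(phantom_spec(iceberg_depth = 5),  # gap is 12 - 8 = 4 mm
               "exceeds")
  expect_error(phantom_spec(volume_increase_fraction = 0.5), "air cavity")
  expect_error(phantom_spec(inner_radius = 7), "cavity_radius")
})

test_that("identical seeds give bit-identical bundles, different seeds differ", {
  spec <- phantom_spec(seed = 123L)
  b1 <- generate_phantom(spec)
  b2 <- generate_phantom(spec)
  expect_identical(b1$hu_image, b2$hu_image)
  expect_identical(b1$dose_plan_s$dose, b2$dose_plan_s$dose)
  expect_identical(b1$gtv_l$occupancy, b2$gtv_l$occupancy)

  b3 <- generate_phantom(phantom_spec(seed = 124L))
  expect_false(identical(b1$hu_image, b3$hu_image))
})

test_that("the conformal dose model honours its stated bounds", {
  b <- get_default_bundle()
  d <- b$dose_plan_l
  rx <- d$prescription
  occ <- b$ctv_l$occupancy
  rel <- d$dose / rx * 100

  # inside-target dose within the 95-107% window after D95 normalization
  expect_gte(min(rel[occ]), 95)
  expect_lte(max(rel[occ]), 107)
  dvh <- compute_dvh(d, b$ctv_l)
  expect_equal(100 * dose_at_volume(dvh, 0.95) / rx, 100, tolerance = 0.05)

  # far-field: beyond 5 sigma from the target the dose is below 5%
  far <- expand_isotropic(b$ctv_l, 5 * b$spec$penumbra_sigma)
  expect_lt(max(d$dose[!far$occupancy]) / rx, 0.05)

  expect_error(generate_conformal_dose(
    structure_mask(c(0, 0, 0), c(1, 1, 1), array(FALSE, c(4, 4, 4)))),
    "empty")
})

test_that("each plan meets every per-protocol objective on its own target", {
  b <- get_default_bundle()
  for (pair in list(list(b$dose_plan_s, b$ctv_s),
                    list(b$dose_plan_l, b$ctv_l))) {
    v <- evaluate_plan(extract_metrics(pair[[1]], pair[[2]]))
    expect_true(v$accepted)
    expect_true(all(v$classifications == "per_protocol"))
  }
})

test_that("the difference volume falls in the penumbra of the S plan", {
  b <- get_default_bundle()
  delta <- mask_subtract(b$ctv_l, b$ctv_s)
  expect_gt(sum(delta$occupancy), 0)
  rx <- b$dose_plan_s$prescription
  d98_delta <- 100 * dose_at_volume(compute_dvh(b$dose_plan_s, delta), 0.98) / rx
  d98_s <- 100 * dose_at_volume(compute_dvh(b$dose_plan_s, b$ctv_s), 0.98) / rx
  expect_lt(d98_delta, d98_s)
  expect_true(flag_under_coverage(d98_delta)$under_covered)
})

test_that("cohorts are seeded, reproducible and validated", {
  c1 <- generate_cohort(2, seed = 5)
  c2 <- generate_cohort(2, seed = 5)
  expect_identical(c1[[1]]$gtv_l$occupancy, c2[[1]]$gtv_l$occupancy)
  expect_identical(c1[[2]]$dose_plan_s$dose, c2[[2]]$dose_plan_s$dose)

  c3 <- generate_cohort(2, seed = 6)
  expect_false(identical(
    c1[[1]]$ground_truth$volume_s_mm3, c3[[1]]$ground_truth$volume_s_mm3))

  # drawn parameters vary between cases
  expect_false(identical(c1[[1]]$spec$outer_radius, c1[[2]]$spec$outer_radius))
  expect_error(generate_cohort(0), "n must be")
})
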