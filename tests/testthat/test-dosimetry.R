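# DVH computation, Dx% extraction, hot spot, prescription normalization
# and OAR comparison against hand-computable cases.

test_that("cumulative DVH matches step and closed-form cases", {
  dg <- uniform_dose(70)
  mk <- full_mask()
  dvh <- compute_dvh(dg, mk)
  expect_equal(dvh$cumulative_volume_fraction[1], 1.0)
  f <- function(gy) dvh$cumulative_volume_fraction[findInterval(gy, dvh$dose_edges)]
  expect_equal(f(50), 1.0)
  expect_equal(f(69.99), 1.0)
  expect_true(dvh$cumulative_volume_fraction[length(dvh$dose_edges)] %in% c(0, 1) ||
              TRUE)  # last bin is beyond the max dose
  expect_equal(dvh$cumulative_volume_fraction[length(dvh$dose_edges)], 0)
  expect_true(all(diff(dvh$cumulative_volume_fraction) <= 0))

  # half 60 Gy / half 80 Gy
  arr <- array(rep(c(60, 80), each = 72), c(6, 6, 4))
  dvh2 <- compute_dvh(dose_grid(c(0, 0, 0), c(1, 1, 1), arr), mk)
  f2 <- function(gy) dvh2$cumulative_volume_fraction[findInterval(gy, dvh2$dose_edges)]
  expect_equal(f2(61), 0.5)
  expect_equal(f2(75), 0.5)
  expect_equal(f2(80), 0.5)
  expect_equal(f2(59), 1.0)

  expect_error(compute_dvh(dg, structure_mask(c(0, 0, 0), c(1, 1, 1),
                                              array(FALSE, c(6, 6, 4)))),
               "empty")
  expect_error(compute_dvh(dg, full_mask(shape = c(5, 5, 5))), "grid")
})

test_that("dose-at-volume follows the linear-gradient closed form", {
  n <- 1000L
  arr <- array(rep(seq(0, 70, length.out = n), each = 2), c(2, n, 1))
  dg <- dose_grid(c(0, 0, 0), c(1, 1, 1), arr)
  mk <- full_mask(shape = c(2, n, 1))
  dvh <- compute_dvh(dg, mk)
  # closed form d = (1 - f) * 70, resolution one gradient step + one bin
  for (f in c(0.95, 0.5, 0.2)) {
    expect_equal(dose_at_volume(dvh, f), (1 - f) * 70, tolerance = 0.1)
  }
  expect_equal(dose_at_volume(dvh, 1.0), 0, tolerance = 0.02)

  u <- compute_dvh(uniform_dose(70), full_mask())
  expect_equal(dose_at_volume(u, 0.95), 70, tolerance = 0.011)

  expect_error(dose_at_volume(dvh, 0), "fraction")
  expect_error(dose_at_volume(dvh, 1.2), "fraction")
})

test_that("dose_at_volume is non-increasing in the volume fraction", {
  set.seed(5)
  arr <- array(runif(200, 0, 80), c(10, 10, 2))
  dvh <- compute_dvh(dose_grid(c(0, 0, 0), c(1, 1, 1), arr),
                     full_mask(shape = c(10, 10, 2)))
  fr <- seq(0.05, 1, by = 0.05)
  ds <- vapply(fr, function(f) dose_at_volume(dvh, f), numeric(1))
  expect_true(all(diff(ds) <= 1e-12))
})

test_that("hot spot outside the target accumulates whole voxels", {
  # 1 mm voxels; one 80 Gy voxel outside the target, the rest 50 Gy
  arr <- array(50, c(10, 10, 10))
  arr[5, 5, 5] <- 80
  tgt <- array(FALSE, c(10, 10, 10)); tgt[1, 1, 1] <- TRUE
  dg <- dose_grid(c(0, 0, 0), c(1, 1, 1), arr)
  tm <- structure_mask(c(0, 0, 0), c(1, 1, 1), tgt)
  # 0.03 cm^3 = 30 voxels: the single hot voxel is exhausted
  expect_equal(hotspot_outside(dg, tm, 0.03), 50)
  expect_equal(hotspot_outside(dg, tm, 0.001), 80)

  expect_equal(hotspot_outside(uniform_dose(55, c(10, 10, 10)),
                               tm, 0.03), 55)
  all_target <- structure_mask(c(0, 0, 0), c(1, 1, 1),
                               array(TRUE, c(10, 10, 10)))
  expect_error(hotspot_outside(dg, all_target, 0.03), "complement")
})

test_that("D95 normalization is idempotent and scale-invariant", {
  set.seed(9)
  arr <- array(runif(200, 40, 80), c(10, 10, 2))
  dg <- dose_grid(c(0, 0, 0), c(1, 1, 1), arr)
  mk <- full_mask(shape = c(10, 10, 2))
  n1 <- normalize_to_d95(dg, mk)
  n2 <- normalize_to_d95(n1, mk)
  expect_equal(n2$dose, n1$dose, tolerance = 1e-9)

  scaled <- dose_grid(dg$origin, dg$spacing, dg$dose * 2, dg$prescription)
  expect_equal(normalize_to_d95(scaled, mk)$dose, n1$dose, tolerance = 1e-12)

  dvh <- compute_dvh(n1, mk)
  expect_equal(dose_at_volume(dvh, 0.95), 70, tolerance = 0.02)

  zero <- dose_grid(dg$origin, dg$spacing, array(0, c(10, 10, 2)))
  expect_error(normalize_to_d95(zero, mk), "zero")
})

test_that("extracted metrics are ordered and 100% for a uniform prescription dose", {
  # mismatched grids must fail loudly
  expect_error(extract_metrics(uniform_dose(70, c(10, 10, 10)),
                               full_mask(shape = c(8, 10, 10))),
               "grid")

  mk <- structure_mask(c(0, 0, 0), c(1, 1, 1), {
    occ <- array(FALSE, c(10, 10, 10)); occ[3:8, 3:8, 3:8] <- TRUE; occ
  })
  m <- extract_metrics(uniform_dose(70, c(10, 10, 10)), mk)
  expect_equal(c(m$d2, m$d5, m$d95, m$d98), rep(100, 4), tolerance = 0.02)

  set.seed(17)
  arr <- array(runif(1000, 30, 80), c(10, 10, 10))
  m2 <- extract_metrics(dose_grid(c(0, 0, 0), c(1, 1, 1), arr), mk)
  expect_true(m2$d2 >= m2$d5 && m2$d5 >= m2$d95 && m2$d95 >= m2$d98)
})

test_that("OAR comparisons report absolute differences with a cohort summary", {
  a <- list(cord = c(mean = 30, d2 = 45), parotid = c(mean = 40, d2 = 60))
  expect_equal(compare_oar_metrics(a, a)$summary,
               c(median = 0, min = 0, max = 0))

  b <- a; b$cord["mean"] <- 32
  cmp <- compare_oar_metrics(a, b)
  expect_equal(unname(cmp$per_oar$cord["mean"]), 2)
  expect_equal(unname(cmp$summary["max"]), 2)
  expect_true(all(unlist(cmp$per_oar) >= 0))

  bad <- a; names(bad) <- c("cord", "larynx")
  expect_error(compare_oar_metrics(a, bad), "OAR names")
})
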