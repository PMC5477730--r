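# Seeded synthetic phantom: HU volume with a cylindrical air cavity, a
# C-shaped (annular-sector) soft-tissue target wrapping it, a paired
# lung-window variant extended radially toward the cavity ("the tip of the
# iceberg"), barrier masks, and analytic conformal dose distributions.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Specification of the synthetic S/L phantom
#'
#' Parameters of the seeded phantom generator. The soft-tissue-window
#' target (S) is a C-shaped annular sector wrapping a cylindrical air
#' cavity; the lung-window variant (L) is the same sector extended
#' radially toward the cavity by the *iceberg depth*. By default the
#' depth is solved from the target volume-increase fraction
#' `(V_L - V_S) / V_S` (default 0.09, the typical relative volume gain of
#' lung-window delineation), and the extension must stop at the cavity
#' surface.
#'
#' @param spacing voxel size in mm; the default 1 x 1 x 2 mm mimics a
#'   planning CT with 2 mm axial slices and exercises the anisotropic
#'   distance transform.
#' @param shape grid size in voxels (default 105 x 105 x 41, centred on
#'   the cavity axis with headroom for an 8 mm margin plus penumbra).
#' @param origin first voxel centre (mm).
#' @param cavity_radius air-cavity radius (mm), axis along z through
#'   (0, 0).
#' @param body_radius cylindrical body outline (mm); outside is the
#'   anatomical barrier.
#' @param inner_radius,outer_radius radial extent of the S target (mm).
#' @param angular_extent angular span of the C shape (degrees).
#' @param height z-extent of the target (mm).
#' @param volume_increase_fraction targeted `(V_L - V_S) / V_S`; used to
#'   solve the iceberg depth when `iceberg_depth` is `NULL`.
#' @param iceberg_depth radial extension of the L target toward the
#'   cavity (mm), or `NULL` to solve it from the volume fraction.
#' @param penumbra_sigma dose fall-off scale outside the target (mm).
#' @param margin CTV expansion margin (mm).
#' @param prescription prescription dose (Gy).
#' @param bone_center,bone_radius cylindrical bone barrier (mm), placed to
#'   clip the outer CTV edge.
#' @param seed integer seed governing all random draws (HU texture).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = c(1, 1, 2),
                         shape = c(105L, 105L, 41L),
                         origin = c(-52, -52, -40),
                         cavity_radius = 8,
                         body_radius = 48,
                         inner_radius = 12,
                         outer_radius = 26,
                         angular_extent = 220,
                         height = 30,
                         volume_increase_fraction = 0.09,
                         iceberg_depth = NULL,
                         penumbra_sigma = 3,
                         margin = 8,
                         prescription = 70,
                         bone_center = c(32, 0),
                         bone_radius = 5,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  if (inner_radius <= cavity_radius || outer_radius <= inner_radius) {
    stop("phantom_spec: need cavity_radius < inner_radius < outer_radius")
  }
  .iceberg_depth(spec)  # validate solvability now
  spec
}

# depth of the radial L extension; solved from the volume fraction unless
# given explicitly. The L inner radius r_L satisfies
#   (r_S^2 - r_L^2) / (r_out^2 - r_S^2) = fraction
# and must not cross the cavity surface.
.iceberg_depth <- function(spec) {
  gap <- spec$inner_radius - spec$cavity_radius
  if (!is.null(spec$iceberg_depth)) {
    d <- spec$iceberg_depth
    if (d < 0) stop("phantom_spec: iceberg_depth must be >= 0")
    if (d > gap) {
      stop(sprintf(
        "phantom_spec: iceberg_depth %.2f mm exceeds the %.2f mm gap to the air cavity",
        d, gap))
    }
    return(d)
  }
  f <- spec$volume_increase_fraction
  r_l2 <- spec$inner_radius^2 -
    f * (spec$outer_radius^2 - spec$inner_radius^2)
  if (r_l2 < spec$cavity_radius^2) {
    stop("phantom_spec: the requested volume-increase fraction would push the L target into the air cavity")
  }
  spec$inner_radius - sqrt(r_l2)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: cavity r=%.1f, S target r [%.1f, %.1f] x %.0f deg x %.0f mm\n",
    x$cavity_radius, x$inner_radius, x$outer_radius, x$angular_extent,
    x$height))
  cat(sprintf("  iceberg depth %.2f mm (volume increase %.1f%%), seed %d\n",
              .iceberg_depth(x), 100 * x$volume_increase_fraction,
              as.integer(x$seed)))
  invisible(x)
}

#' Mask of voxels inside a CT display window
#'
#' @param hu 3D array of Hounsfield units.
#' @param origin,spacing grid geometry.
#' @param preset a [window_preset()]; the default lung window spans
#'   `[-1000, 0]` HU.
#' @return a [structure_mask()].
#' @export
window_mask <- function(hu, origin, spacing, preset = window_preset()) {
  stopifnot(inherits(preset, "window_preset"))
  structure_mask(origin, spacing, hu >= preset$hu_min & hu <= preset$hu_max)
}

# annular-sector occupancy on the phantom grid
.sector_mask <- function(spec, r_in) {
  xs <- spec$origin[1] + (seq_len(spec$shape[1]) - 1) * spec$spacing[1]
  ys <- spec$origin[2] + (seq_len(spec$shape[2]) - 1) * spec$spacing[2]
  zs <- spec$origin[3] + (seq_len(spec$shape[3]) - 1) * spec$spacing[3]
  r <- sqrt(outer(xs^2, ys^2, "+"))
  th <- atan2(rep(ys, each = length(xs)), rep(xs, times = length(ys)))
  th <- matrix(th * 180 / pi, length(xs))
  in2d <- r >= r_in & r <= spec$outer_radius &
    abs(th) <= spec$angular_extent / 2
  occ <- array(in2d, spec$shape)
  occ[, , abs(zs) > spec$height / 2] <- FALSE
  occ
}

#' Generate one synthetic phantom bundle
#'
#' Builds the full study object for one synthetic case: the HU volume
#' (air cavity in `[-1000, -900]`, soft tissue in `[0, 80]`, bone in
#' `[700, 1200]`), the paired GTV_S / GTV_L masks, the barrier set (air
#' from the lung-window HU range inside the body, bone, body outline),
#' the derived CTV_S / CTV_L (expansion + cropping), two organ-at-risk
#' masks, and the two conformal plans (Plan_S optimized on CTV_S, Plan_L
#' on CTV_L, both normalized to D95% = prescription). Deterministic given
#' the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_bundle` with the fields above plus
#'   `ground_truth` (exact analytic volumes in mm^3, the iceberg depth =
#'   the true 3D Hausdorff distance between GTV_S and GTV_L, and the
#'   volume-increase fraction).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  depth <- .iceberg_depth(spec)
  xs <- spec$origin[1] + (seq_len(spec$shape[1]) - 1) * spec$spacing[1]
  ys <- spec$origin[2] + (seq_len(spec$shape[2]) - 1) * spec$spacing[2]
  r2d <- sqrt(outer(xs^2, ys^2, "+"))
  nz <- spec$shape[3]

  cavity2d <- r2d <= spec$cavity_radius
  body2d <- r2d <= spec$body_radius
  bone2d <- outer((xs - spec$bone_center[1])^2,
                  (ys - spec$bone_center[2])^2, "+") <= spec$bone_radius^2

  hu <- .with_seed(spec$seed, {
    h <- array(runif(prod(spec$shape), -1000, -950), spec$shape)  # ambient air
    tissue <- array(body2d, spec$shape)
    h[tissue] <- runif(sum(tissue), 0, 80)
    cav <- array(cavity2d, spec$shape)
    h[cav] <- runif(sum(cav), -1000, -905)
    bone3 <- array(bone2d & body2d, spec$shape)
    h[bone3] <- runif(sum(bone3), 700, 1200)
    h
  })

  body_mask <- structure_mask(spec$origin, spec$spacing,
                              array(body2d, spec$shape))
  lung_window <- window_mask(hu, spec$origin, spec$spacing, window_preset())
  air <- mask_intersect(lung_window, body_mask)
  bone <- structure_mask(spec$origin, spec$spacing,
                         array(bone2d & body2d, spec$shape))
  anatomical <- structure_mask(spec$origin, spec$spacing,
                               array(!body2d, spec$shape))
  barriers <- barrier_set(air, bone, anatomical)

  gtv_s <- structure_mask(spec$origin, spec$spacing,
                          .sector_mask(spec, spec$inner_radius))
  gtv_l <- structure_mask(spec$origin, spec$spacing,
                          .sector_mask(spec, spec$inner_radius - depth))
  ctv_s <- build_ctv(gtv_s, spec$margin, barriers)
  ctv_l <- build_ctv(gtv_l, spec$margin, barriers)

  dose_plan_s <- generate_conformal_dose(ctv_s, spec$penumbra_sigma,
                                         spec$prescription)
  dose_plan_l <- generate_conformal_dose(ctv_l, spec$penumbra_sigma,
                                         spec$prescription)

  # organs at risk: a cord-like posterior cylinder and a parotid-like ball
  cord2d <- outer((xs + 40)^2, ys^2, "+") <= 16
  cord <- structure_mask(spec$origin, spec$spacing, array(cord2d, spec$shape))
  zs <- spec$origin[3] + (seq_len(nz) - 1) * spec$spacing[3]
  par_occ <- array(FALSE, spec$shape)
  for (k in seq_len(nz)) {
    rr <- 64 - zs[k]^2
    if (rr > 0) par_occ[, , k] <- outer(xs^2, (ys - 42)^2, "+") <= rr
  }
  parotid <- structure_mask(spec$origin, spec$spacing, par_occ)

  ang <- spec$angular_extent * pi / 180
  vol_s <- ang / 2 * (spec$outer_radius^2 - spec$inner_radius^2) * spec$height
  r_l <- spec$inner_radius - depth
  vol_l <- ang / 2 * (spec$outer_radius^2 - r_l^2) * spec$height

  structure(list(
    spec = spec,
    hu_image = hu,
    gtv_s = gtv_s, gtv_l = gtv_l,
    barriers = barriers,
    ctv_s = ctv_s, ctv_l = ctv_l,
    dose_plan_s = dose_plan_s, dose_plan_l = dose_plan_l,
    oars = list(cord = cord, parotid = parotid),
    ground_truth = list(
      volume_s_mm3 = vol_s,
      volume_l_mm3 = vol_l,
      iceberg_depth_mm = depth,
      hd3d_mm = depth,
      volume_increase_fraction = (vol_l - vol_s) / vol_s)
  ), class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "phantom_bundle: GTV_S %.1f cm^3, GTV_L %.1f cm^3 (+%.1f%%), iceberg %.2f mm\n",
    gt$volume_s_mm3 / 1000, gt$volume_l_mm3 / 1000,
    100 * gt$volume_increase_fraction, gt$iceberg_depth_mm))
  invisible(x)
}

#' Analytic conformal dose distribution around a target
#'
#' A deterministic stand-in for an optimized plan: the dose is a function
#' of the signed Euclidean distance `s` to the target surface (voxel-centre
#' distance transform; `s > 0` outside). Inside the target the dose rises
#' gently with depth (up to +5% at the core, mimicking the mild central
#' heterogeneity of clinical plans); outside it falls off as a Gaussian
#' penumbra `exp(-s^2 / (2 sigma^2))`, which is below 5% of prescription
#' beyond `5 sigma`. The grid is then normalized so the target D95%
#' equals the prescription, which keeps the whole in-target dose within
#' the 95-107% protocol window.
#'
#' @param target non-empty target [structure_mask()].
#' @param penumbra_sigma fall-off scale (mm).
#' @param prescription prescription dose (Gy).
#' @return a normalized [dose_grid()].
#' @export
generate_conformal_dose <- function(target, penumbra_sigma = 3,
                                    prescription = 70) {
  stopifnot(inherits(target, "structure_mask"))
  if (!any(target$occupancy)) stop("generate_conformal_dose: empty target")
  occ <- as.logical(target$occupancy)
  d_out <- sqrt(.edt_squared(occ, target$shape, target$spacing))
  d_in <- sqrt(.edt_squared(!occ, target$shape, target$spacing))
  s <- d_out - d_in
  g <- ifelse(s >= 0,
              exp(-s^2 / (2 * penumbra_sigma^2)),
              1 + 0.05 * (1 - exp(s / 2)))
  dose <- dose_grid(target$origin, target$spacing,
                    array(prescription * g, target$shape),
                    prescription = prescription)
  normalize_to_d95(dose, target, prescription)
}

#' Generate a cohort of phantom bundles
#'
#' Draws per-case parameters from fixed uniform ranges around the spec
#' defaults — volume-increase fraction U(0.05, 0.13), outer radius
#' U(24, 27) mm, angular extent U(200, 240) degrees, target height from
#' {26, 30, 34} mm — and generates one bundle per case. One global seed
#' governs the draws; each bundle receives a derived sub-seed (fixed
#' offset), so cohorts are exactly reproducible.
#'
#' @param n number of cases (the emulated study size is 14).
#' @param spec base [phantom_spec()].
#' @param seed integer cohort seed.
#' @return list of `phantom_bundle` objects.
#' @export
generate_cohort <- function(n = 14, spec = phantom_spec(), seed = spec$seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("generate_cohort: n must be >= 1")
  }
  n <- as.integer(n)
  draws <- .with_seed(seed, {
    list(frac = runif(n, 0.05, 0.13),
         outer = runif(n, 24, 27),
         ang = runif(n, 200, 240),
         height = sample(c(26, 30, 34), n, replace = TRUE))
  })
  lapply(seq_len(n), function(i) {
    si <- spec
    si$volume_increase_fraction <- draws$frac[i]
    si$outer_radius <- draws$outer[i]
    si$angular_extent <- draws$ang[i]
    si$height <- draws$height[i]
    si$seed <- as.integer(seed) + i
    generate_phantom(si)
  })
}
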