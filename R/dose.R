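#' Scalar dose grid
#'
#' A dose distribution in Gy on a regular voxel grid, with the
#' prescription dose it refers to (all relative metrics are expressed as a
#' percentage of this prescription). Shares the voxel-centre geometry
#' convention of [structure_mask()].
#'
#' @param origin,spacing grid geometry (mm), as in [structure_mask()].
#' @param dose 3D numeric array of voxel doses (Gy), non-negative.
#' @param prescription prescription dose in Gy (default 70).
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(origin, spacing, dose, prescription = 70) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!is.array(dose) || length(dim(dose)) != 3L) stop("dose must be a 3D array")
  storage.mode(dose) <- "double"
  if (any(dose < 0)) stop("dose must be non-negative everywhere")
  if (!is.finite(prescription) || prescription <= 0) {
    stop("prescription must be positive")
  }
  structure(list(origin = origin, spacing = spacing, shape = dim(dose),
                 dose = dose, prescription = prescription),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d voxels, prescription %.4g Gy, max %.4g Gy\n",
              x$shape[1], x$shape[2], x$shape[3], x$prescription, max(x$dose)))
  invisible(x)
}

#' Cumulative dose-volume histogram of a structure
#'
#' Cumulative DVH from voxel-centre dose values inside the mask:
#' `cumulative_volume_fraction[i]` is the fraction of the structure volume
#' receiving at least `dose_edges[i]`. The curve starts at 1 for dose 0
#' and is non-increasing.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] on the same grid.
#' @param bin_width histogram bin width in Gy. The default 0.01 Gy keeps
#'   Dx% interpolation well below the 0.1 percentage-point reporting
#'   precision at a 70 Gy prescription.
#' @return an object of class `dvh_curve` with `dose_edges`,
#'   `cumulative_volume_fraction`, the structure volume (cm^3) and the
#'   prescription.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  .check_grid(dose, mask, "compute_dvh")
  d <- dose$dose[mask$occupancy]
  if (!length(d)) stop("compute_dvh: empty mask")
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  sd_ <- sort(d)
  n <- length(d)
  # fraction of voxels with dose >= edge
  frac <- (n - findInterval(edges - 1e-12, sd_)) / n
  structure(list(dose_edges = edges, cumulative_volume_fraction = frac,
                 volume_cm3 = length(d) * prod(mask$spacing) / 1000,
                 prescription = dose$prescription),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve: %.2f cm^3, dose range [0, %.4g] Gy, %d bins\n",
              x$volume_cm3, max(x$dose_edges), length(x$dose_edges)))
  invisible(x)
}

#' Dose received by at least a given volume fraction (Dx%)
#'
#' The largest dose `d` with cumulative volume fraction at least
#' `volume_fraction`, linearly interpolated between histogram bin edges.
#' `dose_at_volume(dvh, 0.95)` is the conventional D95%.
#'
#' @param dvh a [compute_dvh()] curve.
#' @param volume_fraction in (0, 1].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_fraction) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (!is.finite(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction > 1) {
    stop("dose_at_volume: volume_fraction must be in (0, 1]")
  }
  e <- dvh$dose_edges
  f <- dvh$cumulative_volume_fraction
  ok <- which(f >= volume_fraction)
  i <- max(ok)
  if (i == length(e)) return(e[i])
  # interpolate within the bin where the curve drops through the fraction
  if (f[i] == f[i + 1L]) return(e[i])
  e[i] + (e[i + 1L] - e[i]) * (f[i] - volume_fraction) / (f[i] - f[i + 1L])
}

#' Hottest small volume outside a target
#'
#' The near-maximum dose outside the target: the minimum dose among the
#' hottest voxels of the target complement whose accumulated volume first
#' reaches `volume_cm3` (i.e. D_{0.03 cm^3} of the complement by default).
#' Whole voxels are accumulated without partial-voxel interpolation, so
#' the result is bit-stable.
#'
#' @param dose a [dose_grid()].
#' @param target the target [structure_mask()] on the same grid.
#' @param volume_cm3 hot-spot volume (cm^3), default 0.03.
#' @return dose in Gy.
#' @export
hotspot_outside <- function(dose, target, volume_cm3 = 0.03) {
  stopifnot(inherits(dose, "dose_grid"), inherits(target, "structure_mask"))
  .check_grid(dose, target, "hotspot_outside")
  d <- dose$dose[!target$occupancy]
  voxel_cm3 <- prod(dose$spacing) / 1000
  if (length(d) * voxel_cm3 < volume_cm3) {
    stop("hotspot_outside: complement volume smaller than the hot-spot volume")
  }
  k <- ceiling(volume_cm3 / voxel_cm3)
  sort(d, decreasing = TRUE)[k]
}

#' Normalize a plan so the target D95% equals the prescription
#'
#' Scales every voxel by one factor such that the dose received by at
#' least 95% of the target volume equals the prescription. The D95% used
#' for the factor is the exact voxel-dose order statistic (not the binned
#' DVH), which makes the operation idempotent and exactly commuting with
#' uniform dose scaling.
#'
#' @param dose a [dose_grid()].
#' @param target non-empty target [structure_mask()].
#' @param prescription prescription in Gy; defaults to the grid's.
#' @return the rescaled [dose_grid()].
#' @export
normalize_to_d95 <- function(dose, target, prescription = dose$prescription) {
  stopifnot(inherits(dose, "dose_grid"), inherits(target, "structure_mask"))
  .check_grid(dose, target, "normalize_to_d95")
  d <- dose$dose[target$occupancy]
  if (!length(d)) stop("normalize_to_d95: empty target")
  n <- length(d)
  d95 <- sort(d, decreasing = TRUE)[ceiling(0.95 * n)]
  if (d95 <= 0) stop("normalize_to_d95: target D95% is zero")
  dose_grid(dose$origin, dose$spacing, dose$dose * (prescription / d95),
            prescription = prescription)
}

#' Extract the standard target dose metrics
#'
#' D2%, D5%, D95% and D98% of a structure plus the hot spot outside a
#' target, all expressed as percent of the prescription.
#'
#' @param dose a [dose_grid()].
#' @param structure the structure whose DVH is evaluated.
#' @param target_for_hotspot the target whose *complement* defines the hot
#'   spot (defaults to `structure`).
#' @param bin_width DVH bin width in Gy.
#' @param hotspot_cm3 hot-spot volume (cm^3).
#' @return an object of class `dose_metrics` with fields `d2`, `d5`,
#'   `d95`, `d98`, `hotspot_outside` (percent of prescription) and
#'   `prescription` (Gy).
#' @export
extract_metrics <- function(dose, structure, target_for_hotspot = structure,
                            bin_width = 0.01, hotspot_cm3 = 0.03) {
  dvh <- compute_dvh(dose, structure, bin_width)
  rx <- dose$prescription
  pct <- function(gy) 100 * gy / rx
  structure(list(
    d2 = pct(dose_at_volume(dvh, 0.02)),
    d5 = pct(dose_at_volume(dvh, 0.05)),
    d95 = pct(dose_at_volume(dvh, 0.95)),
    d98 = pct(dose_at_volume(dvh, 0.98)),
    hotspot_outside = pct(hotspot_outside(dose, target_for_hotspot,
                                          hotspot_cm3)),
    prescription = rx
  ), class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf(
    "dose_metrics (%% of %.4g Gy): D2 %.1f  D5 %.1f  D95 %.1f  D98 %.1f  hotspot %.1f\n",
    x$prescription, x$d2, x$d5, x$d95, x$d98, x$hotspot_outside))
  invisible(x)
}

#' Compare organ-at-risk metrics between two plans
#'
#' Takes two plans' OAR metric tables (named list: OAR name to named
#' numeric vector of metrics, in percent of prescription) and reports the
#' absolute per-metric differences in percentage points, with the median,
#' minimum and maximum across all OAR/metric combinations.
#'
#' @param metrics_a,metrics_b named lists with identical OAR names and
#'   identical metric names per OAR.
#' @return list with `per_oar` (list of named absolute differences) and
#'   `summary` (named vector `median`, `min`, `max`).
#' @export
compare_oar_metrics <- function(metrics_a, metrics_b) {
  if (!setequal(names(metrics_a), names(metrics_b)) ||
      is.null(names(metrics_a))) {
    stop("compare_oar_metrics: OAR names differ between plans")
  }
  per <- lapply(names(metrics_a), function(oar) {
    a <- metrics_a[[oar]]; b <- metrics_b[[oar]]
    if (!setequal(names(a), names(b)) || is.null(names(a))) {
      stop(sprintf("compare_oar_metrics: metric names differ for OAR '%s'", oar))
    }
    abs(a - b[names(a)])
  })
  names(per) <- names(metrics_a)
  all_d <- unlist(per, use.names = FALSE)
  list(per_oar = per,
       summary = c(median = median(all_d), min = min(all_d), max = max(all_d)))
}
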