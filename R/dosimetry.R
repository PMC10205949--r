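#' Voxel grid of activity concentration
#'
#' Minimal container for a 3-D PET activity-concentration map used by the
#' relative-threshold segmentation. Values are Bq/ml at voxel centres.
#'
#' @param values A 3-D numeric array, all values >= 0.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3), > 0.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (any(values < 0) || anyNA(values)) {
    stop("activity concentrations must be non-negative", call. = FALSE)
  }
  voxel_size <- rep_len(as.double(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(list(values = values, voxel_size = voxel_size),
            class = "voxel_grid")
}

# voxel volume in ml (= cm^3); voxel_size is in mm
voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

#' Relative-threshold segmentation of a hot spot
#'
#' Segments the voxels whose concentration is at least
#' `fraction * max(grid)` (the Th10/Th40 operator for `fraction` 0.10 and
#' 0.40). The global maximum always qualifies, so the mask is never empty.
#' No connected-component filtering is applied: the operator mirrors a
#' manual VOI drawn around a single extravasation depot.
#'
#' @param grid A [voxel_grid()] with a positive maximum.
#' @param fraction Threshold fraction in (0, 1].
#' @return An object of class `segmentation_result` with fields
#'   `threshold_fraction`, `volume` (cm^3), `mean_concentration` (Bq/ml)
#'   and `n_voxels`.
#' @export
segment_threshold <- function(grid, fraction) {
  stopifnot(inherits(grid, "voxel_grid"), fraction > 0, fraction <= 1)
  peak <- max(grid$values)
  if (peak <= 0) stop("grid has no positive voxel", call. = FALSE)
  mask <- grid$values >= fraction * peak
  n <- sum(mask)
  structure(list(threshold_fraction = fraction,
                 volume = n * voxel_volume_ml(grid),
                 mean_concentration = mean(grid$values[mask]),
                 n_voxels = n),
            class = "segmentation_result")
}

#' Residual activity at the injection site, decay-corrected
#'
#' The activity seen at imaging time is the product of the mean segmented
#' concentration (Bq/ml) and the segmented volume (ml). Because imaging
#' happens `uptake_time` minutes after injection, the residual activity
#' A_RS at injection time is recovered by multiplying with the physical
#' decay factor `2^(uptake_time / half_life)` (physical decay only — no
#' biological clearance model, a deliberately conservative choice).
#'
#' @param seg A [segment_threshold()] result, or any list with `volume`
#'   (cm^3) and `mean_concentration` (Bq/ml).
#' @param uptake_time Minutes between injection and imaging (default 60).
#' @param half_life Physical half-life in minutes (default 109.771,
#'   fluorine-18).
#' @return An object of class `residual_activity_estimate` with
#'   `activity_at_imaging` (Bq), `decay_factor`, `a_rs` (Bq) and
#'   `half_life` (min).
#' @examples
#' seg <- list(volume = 3.7, mean_concentration = 47812.4)
#' residual_activity(seg, uptake_time = 60)
#' @export
residual_activity <- function(seg, uptake_time = 60, half_life = 109.771) {
  if (!is.finite(uptake_time) || uptake_time < 0) {
    stop("uptake_time must be >= 0 min", call. = FALSE)
  }
  if (!is.finite(half_life) || half_life <= 0) {
    stop("half_life must be > 0 min", call. = FALSE)
  }
  stopifnot(seg$volume > 0, seg$mean_concentration > 0)
  act <- seg$mean_concentration * seg$volume
  decay <- 2^(uptake_time / half_life)
  structure(list(activity_at_imaging = act,
                 decay_factor = decay,
                 a_rs = act * decay,
                 half_life = half_life,
                 uptake_time = uptake_time),
            class = "residual_activity_estimate")
}

#' Interpolate a sphere-model dose factor at a given mass
#'
#' Log-log linear interpolation between the bracketing table rows: sphere
#' S-values are close to a power law in mass, so interpolating
#' `log(dose_factor)` against `log(mass)` is exact at the nodes and
#' accurate between them. Queries outside the tabulated mass range are
#' refused unless `extrapolate = TRUE`.
#'
#' @param table A [sphere_dose_table()].
#' @param mass Sphere mass in g (for water spheres, numerically equal to
#'   the segmented volume in ml).
#' @param extrapolate Allow log-log extrapolation beyond the table range.
#' @return Dose factor in mGy/MBq.
#' @export
interpolate_dose_factor <- function(table, mass, extrapolate = FALSE) {
  stopifnot(inherits(table, "sphere_dose_table"), is.finite(mass), mass > 0)
  m <- table$mass_g
  f <- table$dose_factor_mGy_per_MBq
  if (!extrapolate && (mass < min(m) || mass > max(m))) {
    stop(sprintf("mass %.3g g outside table range [%.3g, %.3g] g; ",
                 mass, min(m), max(m)),
         "set extrapolate = TRUE to allow log-log extrapolation",
         call. = FALSE)
  }
  exp(stats::approx(log(m), log(f), xout = log(mass), rule = 2)$y +
        loglog_extrap(log(m), log(f), log(mass)))
}

# approx(rule = 2) clamps outside the range; add the linear continuation
# of the end segments when extrapolating
loglog_extrap <- function(lx, ly, q) {
  n <- length(lx)
  if (q < lx[1L]) {
    (q - lx[1L]) * (ly[2L] - ly[1L]) / (lx[2L] - lx[1L])
  } else if (q > lx[n]) {
    (q - lx[n]) * (ly[n] - ly[n - 1L]) / (lx[n] - lx[n - 1L])
  } else 0
}

#' Self-dose of the infiltrated tissue
#'
#' Absorbed dose to the extravasation depot under the unit-density sphere
#' model: `Gy = (A_RS / 1e6) [MBq] * dose_factor [mGy/MBq] / 1000`.
#'
#' @param a_rs Residual activity in Bq (decay-corrected to injection time).
#' @param dose_factor Sphere-model dose factor in mGy/MBq.
#' @param sphere_mass Optional sphere mass in g, recorded in the report.
#' @return An object of class `dose_report` with `sphere_mass`,
#'   `dose_factor` and `self_dose` (Gy).
#' @examples
#' self_dose(6671178.9, 22.4)$self_dose  # 0.149 Gy
#' @export
self_dose <- function(a_rs, dose_factor, sphere_mass = NA_real_) {
  stopifnot(a_rs >= 0, dose_factor >= 0)
  structure(list(sphere_mass = sphere_mass,
                 dose_factor = dose_factor,
                 a_rs = a_rs,
                 self_dose = (a_rs / 1e6) * dose_factor / 1000),
            class = "dose_report")
}
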