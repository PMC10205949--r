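#' Dose-rate curve from a wearable detector
#'
#' Container for one arm's ambient dose equivalent rate H*(10) time series,
#' as recorded by a wearable gamma detector during radiopharmaceutical
#' administration (nominal 1 Hz sampling).
#'
#' @param times Numeric vector of sample times in seconds since the start of
#'   acquisition. Must be strictly increasing.
#' @param values Numeric vector of dose rates in uSv/h, same length as
#'   `times`, all non-negative.
#' @param arm Either `"injection"` or `"contralateral"`.
#' @param detector_id Optional free-text detector identifier.
#'
#' @return An object of class `dose_rate_curve`: a list with elements
#'   `times`, `values`, `arm` and `detector_id`.
#' @examples
#' crv <- dose_rate_curve(0:9, c(0, 0, 5, 900, 420, 200, 130, 110, 105, 102),
#'                        arm = "injection")
#' crv
#' @export
dose_rate_curve <- function(times, values, arm = c("injection", "contralateral"),
                            detector_id = NA_character_) {
  arm <- match.arg(arm)
  times <- as.double(times)
  values <- as.double(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a dose-rate curve needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("non-numeric or missing values in dose-rate curve", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("non-increasing times in ", arm, " curve", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("negative dose-rate values are not allowed", call. = FALSE)
  }
  structure(
    list(times = times, values = values, arm = arm,
         detector_id = as.character(detector_id)),
    class = "dose_rate_curve"
  )
}

#' @export
print.dose_rate_curve <- function(x, ...) {
  cat(sprintf("<dose_rate_curve> %s arm, %d samples, t = [%g, %g] s, max %.1f uSv/h\n",
              x$arm, length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' @export
length.dose_rate_curve <- function(x) length(x$times)

# median sampling interval; curves are nominally 1 Hz but detectors drift
curve_dt <- function(curve) stats::median(diff(curve$times))

# TRUE when sampling is uniform to within `tol` of the median interval
is_uniform <- function(curve, tol = 1e-6) {
  d <- diff(curve$times)
  all(abs(d - stats::median(d)) <= tol * max(stats::median(d), 1))
}

# subset of a curve with times in [from, to] (closed)
curve_slice <- function(curve, from, to) {
  keep <- curve$times >= from & curve$times <= to
  dose_rate_curve(curve$times[keep], curve$values[keep], arm = curve$arm,
                  detector_id = curve$detector_id)
}

#' Administration session: the unit of analysis
#'
#' Bundles the injection-arm curve, the optional contralateral-arm curve and
#' the administration metadata (injected activity, uptake time) for one
#' patient's radiopharmaceutical administration.
#'
#' When both curves are present their time ranges must overlap by at least
#' `min_overlap` seconds (default 600 s, i.e. the 10-minute monitoring
#' window). Sessions produced by [cut_window()] are re-validated with a
#' relaxed overlap requirement and carry windowing attributes.
#'
#' @param patient_id Free-text identifier.
#' @param injected_activity Injected activity A_in in MBq, > 0.
#' @param injection_curve A [dose_rate_curve()] with `arm = "injection"`.
#' @param contralateral_curve Optional [dose_rate_curve()] with
#'   `arm = "contralateral"`. When absent the session is analysed in
#'   single-detector mode (injection-arm metrics only).
#' @param uptake_time Minutes between injection and PET acquisition
#'   (default 60).
#' @param min_overlap Minimum required overlap of the two curves in seconds.
#'
#' @return An object of class `administration_session`.
#' @export
administration_session <- function(patient_id, injected_activity,
                                   injection_curve, contralateral_curve = NULL,
                                   uptake_time = 60, min_overlap = 600) {
  if (!inherits(injection_curve, "dose_rate_curve") ||
      injection_curve$arm != "injection") {
    stop("`injection_curve` must be a dose_rate_curve with arm = 'injection'",
         call. = FALSE)
  }
  if (!is.null(contralateral_curve)) {
    if (!inherits(contralateral_curve, "dose_rate_curve") ||
        contralateral_curve$arm != "contralateral") {
      stop("`contralateral_curve` must be a dose_rate_curve with arm = 'contralateral'",
           call. = FALSE)
    }
    ov <- min(max(injection_curve$times), max(contralateral_curve$times)) -
      max(min(injection_curve$times), min(contralateral_curve$times))
    if (ov < min_overlap) {
      stop(sprintf("curves overlap for %.0f s; at least %.0f s required", ov,
                   min_overlap), call. = FALSE)
    }
  }
  injected_activity <- as.double(injected_activity)
  uptake_time <- as.double(uptake_time)
  if (!is.finite(injected_activity) || injected_activity <= 0) {
    stop("injected activity A_in must be > 0 MBq", call. = FALSE)
  }
  if (!is.finite(uptake_time) || uptake_time <= 0) {
    stop("uptake time must be > 0 min", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         injected_activity = injected_activity,
         uptake_time = uptake_time,
         injection_curve = injection_curve,
         contralateral_curve = contralateral_curve),
    class = "administration_session"
  )
}

#' @export
print.administration_session <- function(x, ...) {
  cat(sprintf("<administration_session> patient %s, A_in = %.1f MBq, uptake %g min\n",
              x$patient_id, x$injected_activity, x$uptake_time))
  print(x$injection_curve)
  if (is.null(x$contralateral_curve)) {
    cat("  (single-detector mode: no contralateral curve)\n")
  } else {
    print(x$contralateral_curve)
  }
  invisible(x)
}

has_contralateral <- function(session) !is.null(session$contralateral_curve)

#' Sphere-model dose-factor table
#'
#' Tabulated self-dose factors (mGy per MBq of residual activity) for
#' unit-density spheres, as produced by internal-dosimetry software for the
#' sphere model. The table maps sphere mass (g) to dose factor and is the
#' basis of [interpolate_dose_factor()].
#'
#' @param mass Sphere masses in g, strictly increasing, > 0.
#' @param dose_factor Dose factors in mGy/MBq, > 0, same length as `mass`.
#'
#' @return An object of class `sphere_dose_table` (a data.frame with columns
#'   `mass_g` and `dose_factor_mGy_per_MBq`).
#' @examples
#' tbl <- sphere_dose_table(c(1, 20, 50), c(268, 22.4, 9.4))
#' @export
sphere_dose_table <- function(mass, dose_factor) {
  mass <- as.double(mass)
  dose_factor <- as.double(dose_factor)
  if (length(mass) != length(dose_factor)) {
    stop("`mass` and `dose_factor` must have the same length", call. = FALSE)
  }
  if (length(mass) < 2L) {
    stop(">= 2 rows required for interpolation", call. = FALSE)
  }
  if (anyNA(mass) || anyNA(dose_factor)) {
    stop("missing values in dose table", call. = FALSE)
  }
  if (any(mass <= 0) || any(dose_factor <= 0)) {
    stop("masses and dose factors must be positive", call. = FALSE)
  }
  if (any(diff(mass) <= 0)) {
    stop("masses must be strictly increasing (duplicate or unsorted masses)",
         call. = FALSE)
  }
  structure(
    data.frame(mass_g = mass, dose_factor_mGy_per_MBq = dose_factor),
    class = c("sphere_dose_table", "data.frame")
  )
}
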