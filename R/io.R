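#' Read an administration session from a curve CSV file
#'
#' The curve file is comma-separated with a header line
#' `time_s,dose_rate_usv_h,arm`; `arm` is `"injection"` or
#' `"contralateral"`. Session metadata (patient id, injected activity,
#' uptake time) travels in a separate mapping so the curve file stays a
#' plain sensor export.
#'
#' @param path Path to the curve CSV file.
#' @param meta Named list with `patient_id`, `a_in` (MBq) and optionally
#'   `uptake_time` (min, default 60).
#' @param min_overlap Minimum dual-curve overlap in seconds passed to
#'   [administration_session()].
#'
#' @return An [administration_session()].
#' @seealso [write_session()]
#' @export
read_session <- function(path, meta, min_overlap = 600) {
  if (is.null(meta$patient_id) || is.null(meta$a_in)) {
    stop("`meta` must supply `patient_id` and `a_in`", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "dose_rate_usv_h", "arm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$dose_rate_usv_h)) {
    stop("non-numeric values in time_s/dose_rate_usv_h", call. = FALSE)
  }
  make_curve <- function(arm) {
    rows <- df[df$arm == arm, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    dose_rate_curve(rows$time_s, rows$dose_rate_usv_h, arm = arm)
  }
  inj <- make_curve("injection")
  if (is.null(inj)) stop("no injection-arm rows in ", path, call. = FALSE)
  administration_session(
    patient_id = meta$patient_id,
    injected_activity = meta$a_in,
    uptake_time = if (is.null(meta$uptake_time)) 60 else meta$uptake_time,
    injection_curve = inj,
    contralateral_curve = make_curve("contralateral"),
    min_overlap = min_overlap
  )
}

#' Write an administration session to a curve CSV file
#'
#' Values are formatted with `%.17g` so that a write/read round trip
#' reproduces the doubles bit-identically.
#'
#' @param session An [administration_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  fmt <- function(curve) {
    sprintf("%.17g,%.17g,%s", curve$times, curve$values, curve$arm)
  }
  lines <- c("time_s,dose_rate_usv_h,arm", fmt(session$injection_curve))
  if (has_contralateral(session)) {
    lines <- c(lines, fmt(session$contralateral_curve))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sphere-model dose-factor table
#'
#' Expects two-column comma-separated text with header
#' `mass_g,dose_factor_mGy_per_MBq`. Rows are sorted by mass before
#' validation; duplicate masses are rejected.
#'
#' @param path Path to the CSV file. The package ships a table of
#'   unit-density sphere dose factors for fluorine-18 under
#'   `system.file("extdata", "sphere_dose_factors_f18.csv", package = "extrawatch")`.
#' @return A [sphere_dose_table()].
#' @examples
#' tbl <- read_dose_table(system.file("extdata", "sphere_dose_factors_f18.csv",
#'                                    package = "extrawatch"))
#' interpolate_dose_factor(tbl, 10)
#' @export
read_dose_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mass_g", "dose_factor_mGy_per_MBq")
  if (!all(required %in% names(df))) {
    stop("dose table must have columns mass_g, dose_factor_mGy_per_MBq",
         call. = FALSE)
  }
  ord <- order(df$mass_g)
  sphere_dose_table(df$mass_g[ord], df$dose_factor_mGy_per_MBq[ord])
}

#' Serialise an analysis report to JSON
#'
#' Emits a single JSON document collecting everything the analysis produced
#' for one session: the injection metrics, the class label and the
#' thresholds used, the residual-activity and self-dose estimates and the
#' SUV correction. Fields whose inputs were absent are omitted, so a
#' single-detector session yields a report without arm-difference fields and
#' is flagged `single_detector_mode`.
#'
#' Numbers are written at full double precision (17 significant digits) so a
#' write/parse round trip is lossless to at least 12 significant digits.
#'
#' @param session An [administration_session()].
#' @param metrics An `injection_metrics` object from [compute_metrics()],
#'   or `NULL`.
#' @param label Class label from [classify_session()], or `NULL`.
#' @param models Optional named list of `threshold_model`s used for the
#'   classification (recorded for audit).
#' @param dose_report Optional `dose_report` from [self_dose()].
#' @param residual Optional `residual_activity_estimate` from
#'   [residual_activity()].
#' @param suv Optional `suv_correction` from [suv_correct()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#'
#' @return The JSON string (class `json`), invisibly when written to `path`.
#' @export
write_report <- function(session, metrics = NULL, label = NULL, models = NULL,
                         dose_report = NULL, residual = NULL, suv = NULL,
                         path = NULL) {
  rpt <- list(
    patient_id = session$patient_id,
    a_in_mbq = session$injected_activity,
    uptake_time_min = session$uptake_time,
    single_detector_mode = !has_contralateral(session)
  )
  if (!is.null(metrics)) rpt$metrics <- unclass_metrics(metrics)
  if (!is.null(label)) rpt$label = as.character(label)
  if (!is.null(models)) {
    rpt$thresholds <- lapply(models, function(m) {
      list(metric = m$metric_name, a = m$a, k = m$k,
           decision_limit = m$decision_limit, direction = m$direction)
    })
  }
  if (!is.null(residual)) rpt$residual_activity <- unclass(residual)
  if (!is.null(dose_report)) rpt$dose <- unclass(dose_report)
  if (!is.null(suv)) rpt$suv_correction <- unclass(suv)
  js <- jsonlite::toJSON(rpt, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# flatten an injection_metrics object for serialisation; the delta_r series
# is emitted as parallel arrays
unclass_metrics <- function(m) {
  out <- unclass(m)
  if (!is.null(out$delta_r_series)) {
    out$delta_r_series <- list(time_s = out$delta_r_series$time_s,
                               delta_r_usv_h = out$delta_r_series$delta_r_usv_h)
  }
  out
}
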