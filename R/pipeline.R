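#' Pipeline configuration
#'
#' Bundles every stage's configuration for [run_analysis()]: preprocessing,
#' plateau detection, classification thresholds, the normal/abnormal band
#' and the dosimetry inputs.
#'
#' @param pp_cfg A [preprocess_config()].
#' @param plateau_cfg A [plateau_config()].
#' @param models Named list of [threshold_model()]s (`delta_p_nor`,
#'   `delta_r_6min`), e.g. from [read_threshold_models()]; `NULL` skips
#'   classification.
#' @param classify_cfg A [classify_config()].
#' @param dose_table A [sphere_dose_table()] (or `NULL` to skip dosimetry).
#' @param segmentation Optional list with `volume` (cm^3) and
#'   `mean_concentration` (Bq/ml) — the PET-segmentation statistics of the
#'   extravasation depot, required for the dosimetry/SUV stages.
#' @param suv_in Optional scanner-reported SUV for the correction stage.
#' @param half_life Physical half-life in minutes (default 109.771).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pp_cfg = preprocess_config(),
                            plateau_cfg = plateau_config(),
                            models = NULL,
                            classify_cfg = classify_config(),
                            dose_table = NULL,
                            segmentation = NULL,
                            suv_in = NULL,
                            half_life = 109.771) {
  structure(list(pp_cfg = pp_cfg, plateau_cfg = plateau_cfg, models = models,
                 classify_cfg = classify_cfg, dose_table = dose_table,
                 segmentation = segmentation, suv_in = suv_in,
                 half_life = half_life),
            class = "pipeline_config")
}

#' Run the full analysis workflow on one session
#'
#' Orchestrates preprocess -> metrics -> classify -> (extravasation only)
#' dosimetry -> SUV correction -> report. Non-extravasation sessions still
#' report their metrics and arm-difference trajectory for audit, with the
#' SUV correction coefficient fixed at 1. When the plateau is never
#' reached the returned report has `status = "plateau_not_reached"` and no
#' classification. Deterministic: running twice on the same inputs yields
#' byte-identical reports.
#'
#' @param session An [administration_session()].
#' @param config A [pipeline_config()].
#' @param report_path Optional path for the JSON report.
#' @return A list of class `analysis_result` with elements `status`,
#'   `metrics`, `label`, `residual`, `dose`, `suv` and `report` (the JSON
#'   string).
#' @examples
#' models <- list(
#'   delta_p_nor = threshold_model("delta_p_nor", 0.61, -20,
#'                                 "extravasation_below"),
#'   delta_r_6min = threshold_model("delta_r_6min", 302, 0.05,
#'                                  "extravasation_above"))
#' ses <- generate_session("normal", seed = 3)$session
#' res <- run_analysis(ses, pipeline_config(models = models))
#' res$label
#' @export
run_analysis <- function(session, config = pipeline_config(),
                         report_path = NULL) {
  stopifnot(inherits(session, "administration_session"),
            inherits(config, "pipeline_config"))
  metrics <- tryCatch(
    compute_metrics(session, config$pp_cfg, config$plateau_cfg),
    plateau_not_reached = function(e) e
  )
  if (inherits(metrics, "plateau_not_reached")) {
    report <- write_report(session, path = report_path)
    return(structure(list(status = "plateau_not_reached", metrics = NULL,
                          label = NULL, residual = NULL, dose = NULL,
                          suv = NULL, report = report),
                     class = "analysis_result"))
  }
  label <- if (!is.null(config$models)) {
    classify_session(metrics, config$models, config$classify_cfg)
  }

  residual <- dose <- suv <- NULL
  if (identical(as.character(label), "extravasation") &&
      !is.null(config$segmentation)) {
    residual <- residual_activity(config$segmentation, session$uptake_time,
                                  config$half_life)
    if (!is.null(config$dose_table)) {
      # water sphere: mass in g numerically equals the segmented volume in ml
      mass <- config$segmentation$volume
      dose <- self_dose(residual$a_rs,
                        interpolate_dose_factor(config$dose_table, mass),
                        sphere_mass = mass)
    }
    if (!is.null(config$suv_in)) {
      suv <- suv_correct(config$suv_in,
                         a_in = session$injected_activity,
                         a_rs = residual$a_rs / 1e6)
    }
  } else if (!is.null(label) && !is.null(config$suv_in)) {
    # coefficient pinned to 1 for normal and abnormal administrations
    suv <- suv_correct(config$suv_in, f_rs = 0)
  }
  report <- write_report(session, metrics = metrics, label = label,
                         models = config$models, residual = residual,
                         dose_report = dose, suv = suv, path = report_path)
  structure(list(status = "ok", metrics = metrics, label = label,
                 residual = residual, dose = dose, suv = suv,
                 report = report),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("<analysis_result> status:", x$status, "\n")
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  if (!is.null(x$metrics)) print(x$metrics)
  if (!is.null(x$suv)) print(x$suv)
  invisible(x)
}
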