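#' Plateau-detection configuration
#'
#' The plateau criterion declares the signal stable when, for at least
#' `stability_duration` consecutive seconds, the change of the monitored
#' series between two consecutive instants stays within
#' `stability_tolerance` uSv/h. The arm-difference metric is evaluated
#' `evaluation_delay` seconds (default 6 min) after plateau onset.
#'
#' @param stability_tolerance Maximum consecutive-sample change in uSv/h
#'   (default 15).
#' @param stability_duration Required duration of stability in seconds
#'   (default 60).
#' @param evaluation_delay Delay from plateau onset to the arm-difference
#'   evaluation point in seconds (default 360).
#' @return A list of class `plateau_config`.
#' @export
plateau_config <- function(stability_tolerance = 15, stability_duration = 60,
                           evaluation_delay = 360) {
  stopifnot(stability_tolerance > 0, stability_duration > 0,
            evaluation_delay > 0)
  structure(list(stability_tolerance = stability_tolerance,
                 stability_duration = stability_duration,
                 evaluation_delay = evaluation_delay),
            class = "plateau_config")
}

#' Resample both arms of a session onto a shared 1-second grid
#'
#' The arm-difference series subtracts two asynchronously sampled
#' detectors, so both curves are linearly interpolated onto integer seconds
#' spanning their overlap. Curves already on the same integer grid come
#' back unchanged (linear interpolation is exact at the nodes).
#'
#' @param session An [administration_session()].
#' @param dt Grid spacing in seconds (default 1).
#' @return The resampled session; windowing attributes are preserved.
#' @export
resample_common_grid <- function(session, dt = 1) {
  stopifnot(inherits(session, "administration_session"))
  inj <- session$injection_curve
  con <- session$contralateral_curve
  lo <- min(inj$times); hi <- max(inj$times)
  if (!is.null(con)) {
    lo <- max(lo, min(con$times))
    hi <- min(hi, max(con$times))
  }
  if (hi - lo < 120) {
    stop(sprintf("curves overlap for %.0f s (< 120 s): cannot resample", hi - lo),
         call. = FALSE)
  }
  grid <- seq(ceiling(lo / dt) * dt, floor(hi / dt) * dt, by = dt)
  regrid <- function(curve) {
    v <- stats::approx(curve$times, curve$values, xout = grid)$y
    dose_rate_curve(grid, v, arm = curve$arm, detector_id = curve$detector_id)
  }
  out <- administration_session(
    patient_id = session$patient_id,
    injected_activity = session$injected_activity,
    uptake_time = session$uptake_time,
    injection_curve = regrid(inj),
    contralateral_curve = if (!is.null(con)) regrid(con),
    min_overlap = 120
  )
  for (a in c("t_peak", "dr_max", "windowed", "truncated")) {
    attr(out, a) <- attr(session, a)
  }
  out
}

#' Arm-difference dose-rate series
#'
#' Pointwise difference between the injection-arm and contralateral-arm
#' dose rates on their common grid. Large persistent values indicate
#' activity retained near the injection site; the series may be negative.
#'
#' @param session A session whose two curves share one time grid (see
#'   [resample_common_grid()]).
#' @return A data.frame with columns `time_s` and `delta_r_usv_h`.
#' @export
delta_r_series <- function(session) {
  stopifnot(inherits(session, "administration_session"))
  if (!has_contralateral(session)) {
    stop("no contralateral curve: arm-difference series unavailable ",
         "(single-detector mode)", call. = FALSE)
  }
  inj <- session$injection_curve
  con <- session$contralateral_curve
  if (length(inj$times) != length(con$times) ||
      any(inj$times != con$times)) {
    stop("curves are not on a common grid; call resample_common_grid() first",
         call. = FALSE)
  }
  data.frame(time_s = inj$times, delta_r_usv_h = inj$values - con$values)
}

#' Detect the plateau onset of a series
#'
#' Scans for the first window of `stability_duration` seconds in which the
#' series changes by no more than `stability_tolerance` uSv/h between every
#' pair of consecutive samples; the plateau onset is the start of that
#' window. When no such window exists the function signals a condition of
#' class `plateau_not_reached`, which downstream stages map to an
#' indeterminate classification.
#'
#' @param series A data.frame with columns `time_s` and a value column
#'   (second column used), e.g. the output of [delta_r_series()], on a
#'   uniform grid.
#' @param cfg A [plateau_config()].
#' @param from Optional earliest time at which the plateau may start
#'   (typically the injection peak, so the flat pre-injection baseline is
#'   not mistaken for the plateau).
#' @return Plateau onset time in seconds (absolute, on the series' clock).
#' @export
detect_plateau <- function(series, cfg = plateau_config(), from = NULL) {
  t <- series[[1L]]
  v <- series[[2L]]
  if (!is.null(from)) {
    keep <- t >= from
    t <- t[keep]; v <- v[keep]
  }
  if (length(t) < 2L) {
    stop(plateau_error("series too short for plateau detection"))
  }
  dt <- stats::median(diff(t))
  n_pairs <- max(1L, round(cfg$stability_duration / dt))
  if (length(v) - 1L < n_pairs) {
    stop(plateau_error("series shorter than the stability window"))
  }
  ok <- abs(diff(v)) <= cfg$stability_tolerance
  # first index i with n_pairs consecutive TRUEs starting at i
  run <- cumsum(ok)
  span <- run[n_pairs:length(ok)] - c(0, run)[seq_len(length(ok) - n_pairs + 1L)]
  hit <- which(span == n_pairs)
  if (!length(hit)) {
    stop(plateau_error("plateau not reached"))
  }
  t[hit[1L]]
}

plateau_error <- function(msg) {
  errorCondition(msg, class = c("plateau_not_reached", "error", "condition"))
}

#' Compute the injection metrics of a session
#'
#' Runs the full metric extraction: peak location on the raw injection
#' curve, resampling to a common 1-s grid, peak-anchored windowing,
#' Gaussian smoothing, plateau detection and evaluation of the five
#' injection metrics and their normalised forms:
#'
#' * `dr_in_max` — maximum raw injection-arm dose rate (bolus peak), uSv/h;
#' * `dr_in_mean` — mean smoothed injection-arm dose rate from plateau
#'   onset to the window end, uSv/h;
#' * `t_star` — time from the injection peak to plateau onset, s;
#' * `delta_p` — `dr_in_max - dr_in_mean`, uSv/h;
#' * `delta_p_nor` — `delta_p / dr_in_max` (dimensionless; near 1 for a
#'   clean injection, depressed under extravasation);
#' * `delta_r_series` — arm-difference series over the window, uSv/h;
#' * `delta_r_6min` — arm difference `evaluation_delay` seconds (default
#'   6 min) after plateau onset, uSv/h;
#' * `delta_r_nor` — `delta_r_6min / dr_in_max` (dimensionless).
#'
#' With no contralateral curve (single-detector mode) the plateau is
#' detected on the smoothed injection curve itself and the arm-difference
#' fields are absent.
#'
#' @param session An [administration_session()].
#' @param pp_cfg A [preprocess_config()].
#' @param plateau_cfg A [plateau_config()].
#' @return An object of class `injection_metrics`.
#' @examples
#' ses <- generate_session("extravasation", seed = 42)$session
#' compute_metrics(ses)
#' @export
compute_metrics <- function(session, pp_cfg = preprocess_config(),
                            plateau_cfg = plateau_config()) {
  stopifnot(inherits(session, "administration_session"))
  if (!isTRUE(attr(session, "windowed"))) {
    session <- cut_window(session, pp_cfg)
  }
  session <- resample_common_grid(session)
  t_peak <- attr(session, "t_peak")
  dr_max <- attr(session, "dr_max")
  dual <- has_contralateral(session)

  smooth_ses <- session
  smooth_ses$injection_curve <-
    smooth_curve(session$injection_curve, pp_cfg$smoothing_sigma,
                 pp_cfg$boundary_mode)
  if (dual) {
    smooth_ses$contralateral_curve <-
      smooth_curve(session$contralateral_curve, pp_cfg$smoothing_sigma,
                   pp_cfg$boundary_mode)
  }

  dr_series <- if (dual) delta_r_series(smooth_ses)
  plateau_series <- if (dual) dr_series else {
    data.frame(time_s = smooth_ses$injection_curve$times,
               value = smooth_ses$injection_curve$values)
  }
  t_star_abs <- detect_plateau(plateau_series, plateau_cfg, from = t_peak)

  inj_sm <- smooth_ses$injection_curve
  on_plateau <- inj_sm$times >= t_star_abs
  dr_in_mean <- mean(inj_sm$values[on_plateau])
  delta_p <- dr_max - dr_in_mean

  out <- list(
    dr_in_max = dr_max,
    t_peak = t_peak,
    dr_in_mean = dr_in_mean,
    t_star = t_star_abs - t_peak,
    delta_p = delta_p,
    delta_p_nor = delta_p / dr_max,
    truncated_window = isTRUE(attr(session, "truncated")),
    single_detector_mode = !dual
  )
  if (dual) {
    t_eval <- t_star_abs + plateau_cfg$evaluation_delay
    truncated_eval <- t_eval > max(dr_series$time_s)
    if (truncated_eval) {
      warning("record ends before plateau onset + evaluation delay; ",
              "using the last available sample", call. = FALSE)
      i_eval <- nrow(dr_series)
    } else {
      i_eval <- which.min(abs(dr_series$time_s - t_eval))
    }
    out$delta_r_6min <- dr_series$delta_r_usv_h[i_eval]
    out$delta_r_nor <- out$delta_r_6min / dr_max
    out$truncated_evaluation <- truncated_eval
    out$delta_r_series <- dr_series
  }
  structure(out, class = "injection_metrics")
}

#' @export
print.injection_metrics <- function(x, ...) {
  cat("<injection_metrics>\n")
  cat(sprintf("  DR_in_max   %10.1f uSv/h at t = %.0f s\n", x$dr_in_max, x$t_peak))
  cat(sprintf("  DR_in_mean  %10.1f uSv/h (plateau onset %.0f s after peak)\n",
              x$dr_in_mean, x$t_star))
  cat(sprintf("  delta_p     %10.1f uSv/h   delta_p_nor %.3f\n",
              x$delta_p, x$delta_p_nor))
  if (!is.null(x$delta_r_6min)) {
    cat(sprintf("  delta_r(6')  %9.1f uSv/h   delta_r_nor %.3f\n",
                x$delta_r_6min, x$delta_r_nor))
  } else {
    cat("  (single-detector mode: no arm-difference metrics)\n")
  }
  invisible(x)
}
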