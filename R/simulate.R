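#' Class-conditional curve-generator parameters
#'
#' Describes the stochastic world the synthetic sessions are drawn from.
#' The class-conditional targets are the published cohort statistics of the
#' three administration classes: normalised peak drop
#' N(0.91, 0.06) / N(0.77, 0.23) / N(0.44, 0.05) and arm difference six
#' minutes after plateau onset N(24, 11) / N(150, 22) / N(390, 26) uSv/h
#' for normal / abnormal / extravasation, with ~10% relative detector
#' noise and 1-s sampling. Quantities the cohort statistics do not fix —
#' the peak amplitude scale, the bolus rise time (8-12 s, the reported
#' bolus duration), the post-peak relaxation and contralateral rise time
#' constants, and the abnormal-class slow decay — are stated here once as
#' package defaults; see the methods vignette for the rationale.
#'
#' @param peak_mean,peak_sd,peak_min Injection-peak amplitude distribution
#'   (uSv/h), truncated below at `peak_min`.
#' @param delta_p_nor Named list of `c(mean, sd)` per class for the
#'   normalised peak drop (truncated to `[0.05, 0.98]`: the metric is
#'   bounded by 1 when the plateau is non-negative).
#' @param delta_r Named list of `c(mean, sd)` per class for the
#'   arm-difference target at the evaluation point (uSv/h).
#' @param rise_range Bolus rise time (injection start to peak), uniform
#'   over this range and rounded to the sampling grid so the 1-Hz record
#'   contains the true peak sample (s).
#' @param bolus_shape Gamma-variate shape exponent; larger values sharpen
#'   the bolus spike (default 160, ~2 s full width at half maximum, so the
#'   peak sample stands clear of its neighbours and the raw sampled
#'   maximum is an unbiased peak estimate under multiplicative noise).
#' @param tau_base Time constant of the injection arm's saturating rise
#'   towards its plateau, underneath the bolus spike (s).
#' @param tau_con Contralateral saturating-rise time constant (s).
#' @param abnormal_slow_frac,tau_slow Amplitude (fraction of the peak) and
#'   time constant (s) of the slow plateau decay that distinguishes the
#'   abnormal (venous-retention) class.
#' @param noise_cv Relative standard deviation of the multiplicative
#'   Gaussian detector noise, in `[0, 0.5]` (default 0.10).
#' @param duration,t_inj,dt Record length, injection start time and
#'   sampling interval (s).
#' @return A list of class `class_curve_params`.
#' @export
class_curve_params <- function(
    peak_mean = 1200, peak_sd = 150, peak_min = 800,
    delta_p_nor = list(normal = c(0.91, 0.06),
                       abnormal = c(0.77, 0.23),
                       extravasation = c(0.44, 0.05)),
    delta_r = list(normal = c(24, 11),
                   abnormal = c(150, 22),
                   extravasation = c(390, 26)),
    rise_range = c(8, 12),
    bolus_shape = 160,
    tau_base = 8,
    tau_con = 40,
    abnormal_slow_frac = 0.12,
    tau_slow = 300,
    noise_cv = 0.10,
    duration = 660, t_inj = 60, dt = 1) {
  stopifnot(peak_min > 0, peak_sd >= 0, tau_base > 0, tau_con > 0,
            tau_slow > 0, noise_cv >= 0, noise_cv <= 0.5,
            duration > 0, dt > 0, t_inj >= 0,
            all(c("normal", "abnormal", "extravasation") %in%
                  names(delta_p_nor)),
            all(c("normal", "abnormal", "extravasation") %in% names(delta_r)))
  structure(as.list(environment()), class = "class_curve_params")
}

# Evaluate the noiseless two-arm curve model on a time grid.
# Injection arm = saturating rise to the plateau (tau_base) + a sharp
# gamma-variate bolus-transit spike peaking at t_peak + (abnormal only) a
# slowly decaying retention component. The spike amplitude is set so the
# curve equals dr_max exactly at the (grid-aligned) peak sample.
noiseless_curves <- function(t, truth, params) {
  t0 <- truth$t_peak
  t_inj <- t0 - truth$rise_time
  u <- (t - t_inj) / truth$rise_time
  a <- params$bolus_shape
  spike <- ifelse(u > 0, exp(a * (log(pmax(u, 1e-300)) + 1 - u)), 0)
  base <- ifelse(t > t_inj,
                 truth$plateau_in * (1 - exp(-(t - t_inj) / params$tau_base)),
                 0)
  slow <- ifelse(t > t_inj,
                 truth$slow_amp * exp(-pmax(t - t0, 0) / params$tau_slow),
                 0)
  base_at_peak <- truth$plateau_in *
    (1 - exp(-truth$rise_time / params$tau_base)) + truth$slow_amp
  inj <- base + slow + (truth$dr_max - base_at_peak) * spike
  con <- ifelse(t <= t_inj, 0,
                truth$plateau_con * (1 - exp(-(t - t_inj) / params$tau_con)))
  list(injection = pmax(inj, 0), contralateral = pmax(con, 0))
}

# rejection-sampled session-level ground truth for one class
draw_truth <- function(label, params) {
  dp <- params$delta_p_nor[[label]]
  dr <- params$delta_r[[label]]
  for (i in 1:100) {
    m <- stats::rnorm(1, params$peak_mean, params$peak_sd)
    dpn <- stats::rnorm(1, dp[1], dp[2])
    drt <- stats::rnorm(1, dr[1], dr[2])
    dpn <- min(max(dpn, 0.05), 0.98)
    if (m < params$peak_min) next
    plateau_in <- (1 - dpn) * m
    slow_amp <- if (label == "abnormal") params$abnormal_slow_frac * m else 0
    # the slow component still present at the nominal evaluation point
    slow_at_eval <- slow_amp * exp(-(30 + 360) / params$tau_slow)
    plateau_con <- plateau_in + slow_at_eval - drt
    if (plateau_con < 5) next
    rise <- stats::runif(1, params$rise_range[1], params$rise_range[2])
    rise <- max(params$dt, round(rise / params$dt) * params$dt)
    # spike amplitude must be positive for dr_max to be the global peak
    if (m <= plateau_in * (1 - exp(-rise / params$tau_base)) + slow_amp) next
    return(list(label = label,
                dr_max = m,
                t_peak = params$t_inj + rise,
                rise_time = rise,
                plateau_in = plateau_in,
                plateau_con = plateau_con,
                slow_amp = slow_amp,
                delta_p_nor = dpn,
                delta_r_6min = drt))
  }
  stop("could not draw a consistent session (peak too low for the class ",
       "targets); raise peak_mean/peak_min", call. = FALSE)
}

#' Generate one synthetic administration session
#'
#' Draws session-level ground truth from the class-conditional
#' distributions, evaluates the closed-form two-arm curve model on the
#' sampling grid and applies per-sample multiplicative Gaussian noise. The
#' injection arm is a saturating rise to its plateau with a sharp
#' gamma-variate bolus-transit spike on top; the contralateral arm rises
#' saturatingly to its plateau; the abnormal class adds a slowly decaying
#' retention component on the injection arm. Identical seeds give
#' bit-identical sessions.
#'
#' @param label `"normal"`, `"abnormal"` or `"extravasation"`.
#' @param params A [class_curve_params()].
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param patient_id Identifier stored on the session.
#' @param a_in Injected activity recorded on the session (MBq).
#' @return A list with elements `session` (an [administration_session()])
#'   and `truth` (the ground-truth record, class `ground_truth`).
#' @examples
#' gs <- generate_session("extravasation", seed = 1)
#' gs$truth$delta_p_nor
#' @export
generate_session <- function(label = c("normal", "abnormal", "extravasation"),
                             params = class_curve_params(), seed = NULL,
                             patient_id = "synthetic", a_in = 200) {
  label <- match.arg(label)
  with_seed(seed, {
    truth <- draw_truth(label, params)
    t <- seq(0, params$duration, by = params$dt)
    clean <- noiseless_curves(t, truth, params)
    noisy <- lapply(clean, function(v) {
      if (params$noise_cv == 0) v
      else pmax(v * (1 + params$noise_cv * stats::rnorm(length(v))), 0)
    })
    truth$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
    class(truth) <- "ground_truth"
    list(
      session = administration_session(
        patient_id = patient_id,
        injected_activity = a_in,
        injection_curve = dose_rate_curve(t, noisy$injection,
                                          arm = "injection",
                                          detector_id = "sim-inj"),
        contralateral_curve = dose_rate_curve(t, noisy$contralateral,
                                              arm = "contralateral",
                                              detector_id = "sim-con")),
      truth = truth
    )
  })
}

#' Reconstruct the noiseless curves of a ground-truth record
#'
#' The curve model is closed-form, so the noise-free session is exactly
#' reproducible from its `ground_truth` alone.
#'
#' @param truth A `ground_truth` from [generate_session()].
#' @param params The [class_curve_params()] used to generate it.
#' @return A list with `times`, `injection` and `contralateral` vectors.
#' @export
noiseless_session <- function(truth, params = class_curve_params()) {
  t <- seq(0, params$duration, by = params$dt)
  c(list(times = t), noiseless_curves(t, truth, params))
}

#' Generate a class-labelled cohort of synthetic sessions
#'
#' Per-session seeds are derived from the master seed by a counter-based
#' scheme, so any session can be regenerated independently and two master
#' seeds give different curves with the same class composition.
#'
#' @param n_normal,n_abnormal,n_extravasation Class counts (>= 0, total
#'   >= 1).
#' @param params A [class_curve_params()].
#' @param seed Master seed.
#' @return A list of `generate_session()` results, each with `session` and
#'   `truth`; names are `patient_id`s of the form `sim-###`.
#' @export
generate_cohort <- function(n_normal, n_abnormal, n_extravasation,
                            params = class_curve_params(), seed = 1) {
  n <- c(normal = n_normal, abnormal = n_abnormal,
         extravasation = n_extravasation)
  stopifnot(all(n >= 0), sum(n) >= 1)
  labels <- rep(names(n), n)
  seeds <- (as.double(seed) + 104729 * seq_along(labels)) %% 2147483647
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    out[[i]] <- generate_session(labels[i], params, seed = seeds[i],
                                 patient_id = sprintf("sim-%03d", i))
  }
  names(out) <- sprintf("sim-%03d", seq_along(labels))
  out
}

#' Generate a Gaussian hot-spot voxel phantom
#'
#' A 3-D Gaussian activity-concentration profile, scaled so the
#' grid-integrated activity equals the requested value, on a zero
#' background. Feeds [segment_threshold()] in tests and demonstrations.
#'
#' @param activity_mbq Total extravasated activity in MBq (> 0).
#' @param spot_sigma Gaussian sigma of the depot in mm.
#' @param shape Grid dimensions in voxels (length 3).
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param seed Optional seed; jitters the depot centre by up to half a
#'   voxel so the discretisation is not always grid-aligned.
#' @return A [voxel_grid()] (Bq/ml) with attribute `center` (mm).
#' @export
generate_phantom <- function(activity_mbq, spot_sigma = 10,
                             shape = c(32, 32, 32), voxel_size = 3,
                             seed = NULL) {
  stopifnot(activity_mbq > 0, spot_sigma > 0, length(shape) == 3L)
  voxel_size <- rep_len(as.double(voxel_size), 3L)
  extent <- shape * voxel_size
  if (any(4 * spot_sigma > extent)) {
    stop("spot larger than grid: 4 * spot_sigma exceeds the grid extent",
         call. = FALSE)
  }
  with_seed(seed, {
    center <- extent / 2 +
      if (is.null(seed)) 0 else stats::runif(3, -0.5, 0.5) * voxel_size
    ax <- lapply(1:3, function(k) {
      (seq_len(shape[k]) - 0.5) * voxel_size[k] - center[k]
    })
    r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    prof <- exp(-r2 / (2 * spot_sigma^2))
    vox_ml <- prod(voxel_size) / 1000
    values <- prof * (activity_mbq * 1e6) / (sum(prof) * vox_ml)
    g <- voxel_grid(values, voxel_size)
    attr(g, "center") <- center
    g
  })
}

# run `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
  }
  code
}
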