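#' Logistic threshold model
#'
#' A decision threshold obtained by least-squares fitting of
#' `outcome = 1 / (1 + exp(-k * (metric - a)))` to dichotomous
#' extravasation outcomes. With the decision limit at probability 0.5 the
#' fitted `a` is the threshold. The extravasation side is stored
#' explicitly: for the normalised peak-drop metric extravasations lie
#' *below* the threshold (`k < 0` expected), for the arm-difference metric
#' *above* it.
#'
#' @param metric_name One of `"delta_p_nor"`, `"delta_r_6min"` or a free
#'   name.
#' @param a Threshold (metric units).
#' @param k Logistic slope (per metric unit), non-zero.
#' @param direction `"extravasation_below"` or `"extravasation_above"`.
#' @param ssr Residual sum of squares of the fit (optional).
#' @return A list of class `threshold_model`.
#' @export
threshold_model <- function(metric_name, a, k,
                            direction = c("extravasation_below",
                                          "extravasation_above"),
                            ssr = NA_real_) {
  direction <- match.arg(direction)
  stopifnot(is.finite(a), is.finite(k), k != 0)
  structure(list(metric_name = metric_name, a = a, k = k,
                 decision_limit = 0.5, direction = direction, ssr = ssr),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s: a = %.4g, k = %.4g (%s)\n",
              x$metric_name, x$a, x$k, x$direction))
  invisible(x)
}

#' Fit a logistic decision threshold to dichotomous outcomes
#'
#' Least-squares fit (not maximum likelihood) of the logistic
#' `outcome = 1 / (1 + exp(-k * (metric - a)))` to `(value, outcome)`
#' pairs, with outcome 1 for extravasation. The fit is performed in
#' standardised coordinates `z = (x - mean) / sd` with the slope bounded
#' (|k_z| <= 60, i.e. an effectively step-like sigmoid), which makes the
#' fit exactly equivariant under affine rescaling of the metric and keeps
#' the threshold well-defined when the two outcome groups are perfectly
#' separated. Multi-start initialisation: slopes +-1/SD and +-4/SD, offset
#' at the midpoint of the two outcome-group means.
#'
#' @param values Numeric metric values.
#' @param outcomes Vector of 0/1 outcomes (1 = extravasation).
#' @param metric_name Stored on the returned model.
#' @return A [threshold_model()]; `direction` is inferred from the sign of
#'   the fitted slope.
#' @examples
#' x <- c(0.40, 0.45, 0.85, 0.90, 0.95)
#' y <- c(1, 1, 0, 0, 0)
#' fit_threshold(x, y, "delta_p_nor")
#' @export
fit_threshold <- function(values, outcomes, metric_name = "metric") {
  x <- as.double(values)
  y <- as.double(outcomes)
  if (length(x) != length(y) || length(x) < 4L) {
    stop("need >= 4 (value, outcome) pairs", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0 or 1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be represented", call. = FALSE)
  }
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("all metric values identical: cannot fit", call. = FALSE)
  z <- (x - m) / s
  obj <- function(p) sum((y - stats::plogis(p[1L] * (z - p[2L])))^2)
  a0 <- (mean(z[y == 1]) + mean(z[y == 0])) / 2
  best <- NULL
  for (k0 in c(-1, 1, -4, 4)) {
    fit <- tryCatch(
      stats::optim(c(k0, a0), obj, method = "L-BFGS-B",
                   lower = c(-60, min(z) - 3), upper = c(60, max(z) + 3),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-12)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("logistic fit did not converge", call. = FALSE)
  k_z <- best$par[1L]
  threshold_model(
    metric_name = metric_name,
    a = m + s * best$par[2L],
    k = k_z / s,
    direction = if (k_z < 0) "extravasation_below" else "extravasation_above",
    ssr = best$value
  )
}

#' Classification configuration: the normal/abnormal boundary
#'
#' The extravasation thresholds come from fitted [threshold_model()]s; the
#' boundary between normal and (non-extravasated) abnormal administrations
#' is *not* a fitted quantity. It defaults to the normal-class mean +- 2 SD
#' of each metric (peak drop below 0.79, arm difference above 46 uSv/h) and
#' should be reviewed against local practice.
#'
#' @param delta_p_nor_normal_min Lower edge of the normal band for the
#'   normalised peak drop (default `0.91 - 2 * 0.06`).
#' @param delta_r_normal_max Upper edge of the normal band for the
#'   arm-difference metric in uSv/h (default `24 + 2 * 11`).
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(delta_p_nor_normal_min = 0.91 - 2 * 0.06,
                            delta_r_normal_max = 24 + 2 * 11) {
  structure(list(delta_p_nor_normal_min = delta_p_nor_normal_min,
                 delta_r_normal_max = delta_r_normal_max),
            class = "classify_config")
}

#' Classify an administration session from its metrics
#'
#' A session is labelled `"extravasation"` when *any* available metric
#' crosses its extravasation threshold strictly (normalised peak drop below
#' `a`, or arm difference above `a`) — the OR rule favours sensitivity. A
#' value exactly at the threshold is not extravasation. Otherwise the
#' session is `"abnormal"` when a metric leaves the configured normal band,
#' else `"normal"`. The decision is deterministic and order-independent;
#' when only the injection arm was monitored the decision rests on the peak
#' drop alone and the result carries attribute `single_metric = TRUE`.
#'
#' @param metrics An `injection_metrics` object (or a list with
#'   `delta_p_nor` and optionally `delta_r_6min`).
#' @param models Named list of [threshold_model()]s with elements
#'   `delta_p_nor` and/or `delta_r_6min`.
#' @param cfg A [classify_config()].
#' @return A character scalar: `"normal"`, `"abnormal"` or
#'   `"extravasation"`.
#' @examples
#' models <- list(
#'   delta_p_nor = threshold_model("delta_p_nor", a = 0.61, k = -20,
#'                                 direction = "extravasation_below"),
#'   delta_r_6min = threshold_model("delta_r_6min", a = 302, k = 0.05,
#'                                  direction = "extravasation_above"))
#' classify_session(list(delta_p_nor = 0.44, delta_r_6min = 390), models)
#' @export
classify_session <- function(metrics, models, cfg = classify_config()) {
  dp <- metrics$delta_p_nor
  dr <- metrics$delta_r_6min
  if (is.null(dp)) stop("delta_p_nor is required for classification",
                        call. = FALSE)
  extrav <- FALSE
  if (!is.null(models$delta_p_nor)) {
    extrav <- extrav || crosses(dp, models$delta_p_nor)
  }
  if (!is.null(dr) && !is.null(models$delta_r_6min)) {
    extrav <- extrav || crosses(dr, models$delta_r_6min)
  }
  label <- if (extrav) {
    "extravasation"
  } else if (dp < cfg$delta_p_nor_normal_min ||
             (!is.null(dr) && dr > cfg$delta_r_normal_max)) {
    "abnormal"
  } else {
    "normal"
  }
  attr(label, "single_metric") <- is.null(dr)
  label
}

# strict crossing into the extravasation side
crosses <- function(value, model) {
  if (model$direction == "extravasation_below") value < model$a
  else value > model$a
}

#' Persist threshold models to a JSON file
#'
#' @param models Named list of [threshold_model()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_models <- function(models, path) {
  payload <- lapply(models, function(m) unclass(m))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Read threshold models from a JSON file
#'
#' @param path Path written by [write_threshold_models()].
#' @return Named list of [threshold_model()]s.
#' @export
read_threshold_models <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    threshold_model(m$metric_name, m$a, m$k, m$direction,
                    ssr = if (is.null(m$ssr)) NA_real_ else m$ssr)
  })
}

#' Sample-size specification for an AUC superiority test
#'
#' @param auc_null Null-hypothesis AUC (one-sided test, default 0.80).
#' @param auc_alt Expected AUC under the alternative (default 0.90).
#' @param alpha One-sided type-I error rate (default 0.05).
#' @param power Required power (default 0.90).
#' @param prevalence Prevalence of positive (extravasation) cases
#'   (default 0.06).
#' @return A list of class `sample_size_spec`.
#' @export
sample_size_spec <- function(auc_null = 0.80, auc_alt = 0.90, alpha = 0.05,
                             power = 0.90, prevalence = 0.06) {
  stopifnot(auc_null > 0.5, auc_null < auc_alt, auc_alt < 1,
            alpha > 0, alpha < 1, power > 0, power < 1,
            prevalence > 0, prevalence < 1)
  structure(list(auc_null = auc_null, auc_alt = auc_alt, alpha = alpha,
                 power = power, prevalence = prevalence),
            class = "sample_size_spec")
}

# Hanley-McNeil exponential-approximation variance of an empirical AUC
auc_variance <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Sample size for detecting an AUC above a null value
#'
#' Smallest total number of patients such that the one-sided large-sample
#' z-test of `AUC = auc_null` against `AUC > auc_null` reaches the
#' requested power when the true AUC is `auc_alt`, with
#' `ceiling(prevalence * n)` positive cases. AUC variances use the
#' Hanley-McNeil exponential approximation.
#'
#' @param spec A [sample_size_spec()].
#' @param n_max Search limit (default 1e6).
#' @return Total sample size (integer).
#' @examples
#' sample_size_auc(sample_size_spec(0.80, 0.90, 0.05, 0.90, 0.06))
#' @export
sample_size_auc <- function(spec = sample_size_spec(), n_max = 1e6) {
  stopifnot(inherits(spec, "sample_size_spec"))
  z_a <- stats::qnorm(1 - spec$alpha)
  power_at <- function(n) {
    n_pos <- ceiling(spec$prevalence * n)
    n_neg <- n - n_pos
    if (n_pos < 2 || n_neg < 2) return(0)
    se0 <- sqrt(auc_variance(spec$auc_null, n_pos, n_neg))
    se1 <- sqrt(auc_variance(spec$auc_alt, n_pos, n_neg))
    stats::pnorm((spec$auc_alt - spec$auc_null - z_a * se0) / se1)
  }
  lo <- 4; hi <- 8
  while (power_at(hi) < spec$power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) stop("sample size exceeds n_max; hypotheses too close",
                         call. = FALSE)
  }
  # power_at is monotone in n up to prevalence rounding; bisect then scan
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_at(mid) >= spec$power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
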