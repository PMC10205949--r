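#' SUV correction for an extravasated administration
#'
#' The standardised uptake value assumes the whole injected activity A_in
#' entered circulation. When a fraction `f_rs = A_RS / A_in` stayed at the
#' injection site, only `A_in - A_RS` was available for uptake, so the
#' scanner-reported SUV must be rescaled by
#' `coefficient = A_in / (A_in - A_RS) = 1 / (1 - f_rs)`. Equivalently the
#' percentage SUV correction is `SUV_%CR = 100 * f_rs / (1 - f_rs)` and
#' `coefficient = 1 + SUV_%CR / 100`. For normal and abnormal
#' administrations the coefficient is fixed at 1.
#'
#' @param suv_in Scanner-reported SUV (> 0).
#' @param a_in Injected activity in MBq (required unless `f_rs` is given).
#' @param a_rs Residual activity in MBq, `0 <= a_rs < a_in`.
#' @param f_rs Residual fraction `a_rs / a_in`; may be supplied directly
#'   instead of `a_in`/`a_rs`.
#' @return An object of class `suv_correction` with `suv_in`, `f_rs`,
#'   `suv_pct_cr` (percent), `coefficient` and `suv_corrected`.
#' @examples
#' suv_correct(1.8, f_rs = 0.0596)        # coefficient 1.063
#' suv_correct(2.0, a_in = 165, a_rs = 165 * 0.0204)
#' @export
suv_correct <- function(suv_in, a_in = NULL, a_rs = NULL, f_rs = NULL) {
  stopifnot(is.finite(suv_in), suv_in > 0)
  if (is.null(f_rs)) {
    if (is.null(a_in) || is.null(a_rs)) {
      stop("supply either `f_rs` or both `a_in` and `a_rs`", call. = FALSE)
    }
    stopifnot(a_in > 0, a_rs >= 0)
    if (a_rs >= a_in) {
      stop("residual activity must be smaller than the injected activity",
           call. = FALSE)
    }
    f_rs <- a_rs / a_in
  }
  stopifnot(f_rs >= 0, f_rs < 1)
  coefficient <- 1 / (1 - f_rs)
  structure(list(suv_in = suv_in,
                 f_rs = f_rs,
                 suv_pct_cr = 100 * f_rs / (1 - f_rs),
                 coefficient = coefficient,
                 suv_corrected = suv_in * coefficient),
            class = "suv_correction")
}

#' @export
print.suv_correction <- function(x, ...) {
  cat(sprintf("<suv_correction> f_RS = %.4f, SUV %%CR = %.3f%%, coefficient %.3f\n",
              x$f_rs, x$suv_pct_cr, x$coefficient))
  cat(sprintf("  SUV %.3f -> %.3f\n", x$suv_in, x$suv_corrected))
  invisible(x)
}

#' Fit the metric-to-coefficient correction curve
#'
#' Nonlinear least-squares fit of
#' `coefficient = 1 + exp(-a * (metric - b))` to observed
#' (metric, coefficient) pairs — the arm-difference metric normalised to
#' the peak, or the inverse of the normalised peak drop, against the SUV
#' correction coefficient. Non-extravasation administrations, which have
#' coefficient exactly 1, enter as an optional anchor point.
#'
#' Initialisation regresses `log(coefficient - 1)` on the metric over the
#' points with coefficient > 1 (the model is log-linear there), then
#' refines (a, b) on the full point set including the anchor.
#'
#' @param metric Numeric metric values.
#' @param coefficient Observed SUV correction coefficients (>= 1).
#' @param anchor Optional length-2 numeric `c(metric, coefficient)` for the
#'   cumulative non-extravasation point (coefficient typically exactly 1).
#' @return An object of class `correction_curve_fit` with `a`, `b`, `r2`,
#'   `rmse`, `nrmse`, the fitted points and a `predict`-ready closure.
#' @examples
#' fit <- fit_correction_curve(c(0.41, 0.33, 0.31, 0.38),
#'                             c(1.063, 1.004, 1.003, 1.021),
#'                             anchor = c(0.02, 1))
#' fit$r2
#' @export
fit_correction_curve <- function(metric, coefficient, anchor = NULL) {
  x <- as.double(metric)
  y <- as.double(coefficient)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (!is.null(anchor)) {
    stopifnot(length(anchor) == 2L)
    x <- c(x, anchor[1L])
    y <- c(y, anchor[2L])
  }
  if (length(x) < 3L) stop("need >= 3 points (anchor included)", call. = FALSE)
  if (max(y) - min(y) < 1e-12) {
    stop("degenerate: all coefficients equal", call. = FALSE)
  }
  pos <- y > 1
  if (sum(pos) >= 2L) {
    ll <- stats::lm(log(y[pos] - 1) ~ x[pos])
    a0 <- -unname(stats::coef(ll)[2L])
    b0 <- unname(stats::coef(ll)[1L]) / a0
  } else {
    a0 <- 1 / stats::sd(x)
    b0 <- mean(x)
  }
  obj <- function(p) sum((y - (1 + exp(-p[1L] * (x - p[2L]))))^2)
  best <- NULL
  for (scale in c(1, 0.5, 2)) {
    fit <- tryCatch(
      stats::optim(c(a0 * scale, b0), obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("correction-curve fit did not converge", call. = FALSE)
  a <- best$par[1L]; b <- best$par[2L]
  pred <- 1 + exp(-a * (x - b))
  q <- fit_quality(y, pred)
  structure(list(a = a, b = b, r2 = q["r2"], rmse = q["rmse"],
                 nrmse = q["nrmse"], metric = x, coefficient = y,
                 predicted = pred),
            class = "correction_curve_fit")
}

#' @export
print.correction_curve_fit <- function(x, ...) {
  cat(sprintf("<correction_curve_fit> coefficient = 1 + exp(-a (metric - b))\n"))
  cat(sprintf("  a = %.4g, b = %.4g; R2 = %.4f, RMSE = %.4g, NRMSE = %.4g\n",
              x$a, x$b, x$r2, x$rmse, x$nrmse))
  invisible(x)
}

#' Predict SUV correction coefficients from a fitted curve
#'
#' @param object A [fit_correction_curve()] result.
#' @param metric Metric values at which to predict.
#' @param ... Unused.
#' @return Predicted coefficients (all > 1 by construction of the model).
#' @export
predict.correction_curve_fit <- function(object, metric, ...) {
  1 + exp(-object$a * (metric - object$b))
}

#' Goodness-of-fit summaries
#'
#' `r2 = 1 - SS_res / SS_tot`, `rmse = sqrt(SS_res / n)` and
#' `nrmse = rmse / SD(observed)` with the population (n-denominator) SD.
#'
#' @param observed Observed values.
#' @param predicted Model predictions, same length.
#' @return Named numeric vector `c(r2, rmse, nrmse)`.
#' @export
fit_quality <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  res <- observed - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  rmse <- sqrt(ss_res / length(observed))
  sd_pop <- sqrt(ss_tot / length(observed))
  c(r2 = 1 - ss_res / ss_tot, rmse = rmse, nrmse = rmse / sd_pop)
}
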