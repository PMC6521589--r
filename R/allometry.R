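#' Allometric power-law fit
#'
#' Fits `y = a * x^b` by ordinary least squares of `log(y)` on `log(x)`.
#' The slope `b` is the allometric coefficient (exponent); used to relate
#' whole-body clearance or distribution volume to body weight, or
#' clearance to GFR/eRPF.
#'
#' @param x positive covariate values (e.g. body weight, kg).
#' @param y positive parameter values (e.g. whole-body Cl, mL/min).
#' @return object of class `allometric_fit`: list with `exponent`,
#'   `intercept_ln` (`log(a)`), `r` (correlation of the log-log data),
#'   `n`, and `two_point` flag (TRUE when the fit is an exact two-point
#'   solution).
#' @examples
#' fit_power_law(c(1, 10), c(10, 100))$exponent  # exactly 1
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("allometric regression requires strictly positive values", call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  r <- if (stats::sd(ly) > 0 && stats::sd(lx) > 0) stats::cor(lx, ly) else NA_real_
  structure(list(exponent = unname(stats::coef(fit)[2L]),
                 intercept_ln = unname(stats::coef(fit)[1L]),
                 r = r, n = length(x), two_point = length(x) == 2L),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> y = exp(%.4g) * x^%.4g (n = %d, r = %.3f%s)\n",
              x$intercept_ln, x$exponent, x$n,
              if (is.na(x$r)) NA else x$r,
              if (x$two_point) ", exact two-point" else ""))
  invisible(x)
}

#' Whole-body values from weight-normalised parameters
#'
#' Elementwise product with body weight: mL/(min*kg) becomes mL/min,
#' mL/kg becomes mL. All model parameters in this package are
#' weight-normalised; whole-body values are formed only here, in the
#' allometry/reporting layer.
#'
#' @param values per-kg parameter values.
#' @param body_weights body weights (kg), same length or length 1.
#' @return whole-body values.
#' @examples
#' whole_body(2.3, 3.0)  # 6.9 mL/min
#' @export
whole_body <- function(values, body_weights) {
  if (length(body_weights) != 1L && length(body_weights) != length(values)) {
    stop("'body_weights' must have length 1 or match 'values'", call. = FALSE)
  }
  values * body_weights
}
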