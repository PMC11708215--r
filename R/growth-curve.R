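#' Exponential standard growth curve
#'
#' A two-parameter exponential law `value(t) = amplitude * exp(rate * t)`
#' describing egg-chamber growth. Two kinds are used in practice: an area
#' curve (midsection area in um^2 against age in hours) and an
#' oocyte-percent curve (fraction of the midsection area occupied by the
#' oocyte against age in hours).
#'
#' @param amplitude Value at `t = 0` (um^2 for `kind = "area"`, a
#'   dimensionless fraction for `kind = "oocyte_percent"`). Must be > 0.
#' @param rate Exponential growth rate in 1/hour. Must be > 0.
#' @param kind Either `"area"` or `"oocyte_percent"`.
#' @return An object of class `growth_curve`.
#' @examples
#' area_curve <- growth_curve(273, 0.06, "area")
#' predict(area_curve, t = 0)     # 273
#' invert_time(area_curve, 546)   # log(2) / 0.06, the doubling time
#' @export
growth_curve <- function(amplitude, rate, kind = c("area", "oocyte_percent")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  if (rate <= 0) stop("`rate` must be > 0")
  structure(list(amplitude = amplitude, rate = rate, kind = kind),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve kind=%s>  value(t) = %.6g * exp(%.6g * t)  [t in hours]\n",
              x$kind, x$amplitude, x$rate))
  invisible(x)
}

#' Predict a value from a growth curve
#'
#' @param object A [growth_curve()].
#' @param t Age(s) in hours.
#' @param ... Unused.
#' @return `amplitude * exp(rate * t)`, vectorized over `t`.
#' @export
predict.growth_curve <- function(object, t, ...) {
  object$amplitude * exp(object$rate * t)
}

#' Invert a growth curve: age at which a value is reached
#'
#' Solves `value = amplitude * exp(rate * t)` for `t`. Used to assign an
#' initial age t0 to a live-imaged egg chamber from its first measured
#' midsection area (or oocyte percent).
#'
#' @param curve A [growth_curve()].
#' @param value Observed value(s); must be > 0.
#' @return Age(s) in hours; `invert_time(curve, predict(curve, t)) == t`.
#' @export
invert_time <- function(curve, value) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(!is.finite(value)) || any(value <= 0))
    stop("`value` must be finite and > 0")
  log(value / curve$amplitude) / curve$rate
}

#' Fit an exponential growth curve by log-linear least squares
#'
#' Fits `value = A0 * exp(k * t)` by ordinary least squares on
#' `log(value) ~ t`, i.e. under a multiplicative (lognormal) error model.
#' This matches how positive, exponentially growing size measurements are
#' usually treated and is fully deterministic.
#'
#' @param age Ages in hours.
#' @param value Positive measurements (areas in um^2 or oocyte fractions).
#' @param kind Curve kind, see [growth_curve()].
#' @return A [growth_curve()] with `amplitude = exp(intercept)` and
#'   `rate = slope`.
#' @export
fit_growth_curve <- function(age, value, kind = c("area", "oocyte_percent")) {
  kind <- match.arg(kind)
  stopifnot(length(age) == length(value))
  keep <- is.finite(age) & is.finite(value)
  age <- age[keep]; value <- value[keep]
  if (length(age) < 2L) stop("need at least 2 finite (age, value) points")
  if (any(value <= 0)) stop("all values must be > 0 for a log-linear fit")
  if (diff(range(age)) == 0) stop("degenerate fit: all ages identical")
  fit <- stats::lm.fit(cbind(1, age), log(value))
  growth_curve(amplitude = exp(fit$coefficients[[1L]]),
               rate = fit$coefficients[[2L]], kind = kind)
}

#' Correlation between egg-chamber area and oocyte percent
#'
#' Pearson correlation of `log(area)` against `log(oocyte_fraction)` over
#' chambers carrying both measurements. Both quantities grow exponentially
#' with age, so the log scale is the natural one.
#'
#' @param area Midsection areas in um^2.
#' @param oocyte_fraction Oocyte fractions in (0, 1].
#' @return A list with `r` (correlation coefficient) and `n` (chambers used).
#' @export
area_oocyte_correlation <- function(area, oocyte_fraction) {
  stopifnot(length(area) == length(oocyte_fraction))
  keep <- is.finite(area) & is.finite(oocyte_fraction) &
    area > 0 & oocyte_fraction > 0
  if (sum(keep) < 3L) stop("need at least 3 chambers with both area and oocyte fraction")
  list(r = stats::cor(log(area[keep]), log(oocyte_fraction[keep])),
       n = sum(keep))
}

#' Serialize / deserialize a growth curve as JSON
#'
#' @param curve A [growth_curve()].
#' @param path File path.
#' @return `write_growth_curve` returns `path` invisibly;
#'   `read_growth_curve` returns a [growth_curve()].
#' @export
write_growth_curve <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  jsonlite::write_json(list(amplitude = curve$amplitude, rate = curve$rate,
                            kind = curve$kind),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  growth_curve(x$amplitude, x$rate, x$kind)
}
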