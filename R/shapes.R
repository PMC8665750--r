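# Chromatographic line-shape models.
#
# Three shapes are supported: a plain Gaussian, a skew-normal-scaled Gaussian
# (Gaussian multiplied by 1 + erf term, reproducing fronting/tailing via the
# dimensionless skew alpha) and the exponentially modified Gaussian (EMG,
# Gaussian convolved with an exponential decay of time constant tau).  The EMG
# is evaluated through the scaled complementary error function erfcx so that
# it stays finite for any finite t, including tau << sigma where the naive
# exp(sigma^2/(2 tau^2)) form overflows.

#' Error function
#' @param x numeric vector
#' @return erf(x)
#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# log of the complementary error function, accurate in the far right tail
log_erfc <- function(z) {
  log(2) + stats::pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}

# log of erfcx(z) = exp(z^2) * erfc(z); stable for all z
log_erfcx <- function(z) z^2 + log_erfc(z)

#' Construct chromatographic line-shape parameters
#'
#' @param model one of `"gaussian"`, `"skewed_gaussian"`, `"emg"`.
#' @param amplitude peak amplitude above baseline (> 0, intensity units).
#' @param mu location parameter in seconds (the Gaussian centre; note the
#'   apex of a skewed or EMG peak is displaced from `mu`).
#' @param sigma Gaussian spread in seconds (> 0).
#' @param alpha dimensionless skew (skewed_gaussian only; 0 = symmetric).
#' @param tau exponential time constant in seconds (emg only, > 0).
#' @param baseline constant baseline intensity (>= 0).
#' @return an object of class `ShapeParams`.
#' @export
shape_params <- function(model = c("gaussian", "skewed_gaussian", "emg"),
                         amplitude, mu, sigma, alpha = NULL, tau = NULL,
                         baseline = 0) {
  model <- match.arg(model)
  p <- structure(list(model = model, amplitude = amplitude, mu = mu,
                      sigma = sigma, alpha = alpha, tau = tau,
                      baseline = baseline),
                 class = "ShapeParams")
  validate_shape_params(p)
  p
}

validate_shape_params <- function(p) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num_ok(p$amplitude) || !num_ok(p$mu) || !num_ok(p$sigma) ||
      !num_ok(p$baseline))
    stop("shape parameters must be finite numeric scalars", call. = FALSE)
  if (p$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (p$amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (p$baseline < 0) stop("baseline must be >= 0", call. = FALSE)
  if (p$model == "emg" && (!num_ok(p$tau) || p$tau <= 0))
    stop("emg requires tau > 0", call. = FALSE)
  if (p$model == "skewed_gaussian" && !num_ok(p$alpha))
    stop("skewed_gaussian requires finite alpha", call. = FALSE)
  invisible(p)
}

#' Evaluate a line-shape model
#'
#' Returns `baseline + shape(t)`.  The Gaussian is
#' \eqn{A \exp(-(t-\mu)^2 / 2\sigma^2)}; the skewed Gaussian multiplies it by
#' \eqn{1 + \mathrm{erf}(\alpha (t-\mu) / \sigma\sqrt{2})}; the EMG is
#' \eqn{(A\sigma/\tau)\sqrt{\pi/2}\,
#'   e^{\sigma^2/2\tau^2 - (t-\mu)/\tau}\,
#'   \mathrm{erfc}\!\big((\sigma/\tau - (t-\mu)/\sigma)/\sqrt{2}\big)},
#' evaluated via erfcx so the value is finite for all finite `t`.
#'
#' @param params a [shape_params()] object.
#' @param t numeric vector of times (seconds).
#' @return numeric vector of intensities, same length as `t`.
#' @export
model_eval <- function(params, t) {
  validate_shape_params(params)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("t must be finite numeric", call. = FALSE)
  A <- params$amplitude
  z <- (t - params$mu) / params$sigma
  core <- switch(params$model,
    gaussian = A * exp(-z^2 / 2),
    skewed_gaussian = A * exp(-z^2 / 2) *
      (1 + erf(params$alpha * z / sqrt(2))),
    emg = {
      tau <- params$tau
      w <- (params$sigma / tau - z) / sqrt(2)
      A * params$sigma / tau * sqrt(pi / 2) * exp(-z^2 / 2 + log_erfcx(w))
    }
  )
  params$baseline + core
}

#' Baseline-subtracted model area over an interval
#'
#' Integrates `model_eval(params, t) - baseline` over `[rt_lo, rt_hi]` by
#' adaptive quadrature.  For a Gaussian over its full support this equals
#' \eqn{A \sigma \sqrt{2\pi}}.
#'
#' @param params a [shape_params()] object.
#' @param rt_lo,rt_hi integration bounds in seconds, `rt_lo <= rt_hi`.
#' @return scalar area (intensity * seconds).
#' @export
model_area <- function(params, rt_lo, rt_hi) {
  validate_shape_params(params)
  if (rt_lo > rt_hi) stop("rt_lo must be <= rt_hi", call. = FALSE)
  if (rt_lo == rt_hi) return(0)
  f <- function(t) model_eval(params, t) - params$baseline
  stats::integrate(f, rt_lo, rt_hi, rel.tol = 1e-9,
                   subdivisions = 1000L)$value
}

# Locate the apex of the (baseline-subtracted) shape numerically.
# For a plain Gaussian the apex is mu; skew/EMG displace it.
shape_apex <- function(params) {
  if (params$model == "gaussian")
    return(list(rt = params$mu,
                height = model_eval(params, params$mu) - params$baseline))
  tau <- if (params$model == "emg") params$tau else 0
  lo <- params$mu - 10 * params$sigma
  hi <- params$mu + 10 * params$sigma + 10 * tau
  op <- stats::optimize(function(t) model_eval(params, t),
                        interval = c(lo, hi), maximum = TRUE,
                        tol = .Machine$double.eps^0.5)
  list(rt = op$maximum, height = op$objective - params$baseline)
}

# Find where the baseline-subtracted shape crosses `frac * apex_height` on one
# side of the apex, by bracketing outward then bisection (uniroot).
shape_crossing <- function(params, apex_rt, apex_height, frac, side) {
  target <- params$baseline + frac * apex_height
  step <- params$sigma
  if (params$model == "emg" && side > 0) step <- step + params$tau
  x <- apex_rt
  for (i in seq_len(400L)) {
    x <- x + side * step
    if (model_eval(params, x) < target) break
    if (i == 400L) stop("crossing not bracketed", call. = FALSE)
  }
  lo <- min(x, apex_rt); hi <- max(x, apex_rt)
  stats::uniroot(function(t) model_eval(params, t) - target,
                 lower = lo, upper = hi, tol = 1e-10)$root
}

#' Peak width and asymmetry metrics from a converged fit
#'
#' Computes the full width at half maximum (FWHM), the USP tailing factor at
#' 5% of apex height, `(a + b) / (2 a)` with `a = apex - t_left(5%)` and
#' `b = t_right(5%) - apex`, and the 5%-height peak extent.  Heights are
#' measured above the fitted baseline; crossings are found by bisection on
#' the fitted model.
#'
#' @param fit a [fit_curve()] result with `converged = TRUE`.
#' @return list with `apex_rt`, `apex_height`, `fwhm`, `tailing_factor`,
#'   `rt_min_obs`, `rt_max_obs`.
#' @export
peak_metrics <- function(fit) {
  if (!isTRUE(fit$converged))
    stop("peak metrics are undefined for a non-converged fit", call. = FALSE)
  p <- fit$params
  apex <- shape_apex(p)
  t_l50 <- shape_crossing(p, apex$rt, apex$height, 0.5, -1)
  t_r50 <- shape_crossing(p, apex$rt, apex$height, 0.5, +1)
  t_l05 <- shape_crossing(p, apex$rt, apex$height, 0.05, -1)
  t_r05 <- shape_crossing(p, apex$rt, apex$height, 0.05, +1)
  a <- apex$rt - t_l05
  b <- t_r05 - apex$rt
  list(apex_rt = apex$rt, apex_height = apex$height,
       fwhm = t_r50 - t_l50, tailing_factor = (a + b) / (2 * a),
       rt_min_obs = t_l05, rt_max_obs = t_r05)
}
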