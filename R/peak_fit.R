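# Peak fitting and integration on a single EIC.
#
# The default route fits the EMG model by bounded nonlinear least squares
# (skew-Gaussian as a second attempt), accepts the fit when it converged with
# a relative residual RMSE below `max_residual`, the apex inside the ROI rt
# window and a plausible width, and otherwise falls back to trapezoidal
# integration of the raw data points.  All thresholds live in `fit_config()`.

#' Fitting and pipeline configuration
#'
#' @param model primary line-shape model to try (`"emg"`,
#'   `"skewed_gaussian"` or `"gaussian"`).  When the primary model is
#'   rejected, `"skewed_gaussian"` is tried before falling back to
#'   data-point integration.
#' @param max_residual acceptance threshold on residual RMSE divided by apex
#'   height (dimensionless, default 0.35).
#' @param min_height_k detection rule: a peak is `found` when its apex height
#'   is at least `min_height_k` times the estimated baseline noise sd
#'   (default 3).
#' @param min_found minimum number of samples in which a compound must be
#'   found before its consensus window is refined (default 3).
#' @param rt_pad rt padding (seconds) added around the consensus peak extent
#'   when building refined ROI; `NULL` (default) = one median FWHM.
#' @param mz_pad m/z padding in Da around the consensus m/z (default 0.005).
#' @param workers number of parallel workers for batch annotation.
#' @param seed integer seed for all stochastic components.
#' @return a `FitConfig` list.
#' @export
fit_config <- function(model = c("emg", "skewed_gaussian", "gaussian"),
                       max_residual = 0.35, min_height_k = 3,
                       min_found = 3L, rt_pad = NULL, mz_pad = 0.005,
                       workers = 1L, seed = 42L) {
  model <- match.arg(model)
  stopifnot(max_residual > 0, min_height_k >= 0, min_found >= 1,
            mz_pad >= 0, workers >= 1)
  structure(list(model = model, max_residual = max_residual,
                 min_height_k = min_height_k, min_found = as.integer(min_found),
                 rt_pad = rt_pad, mz_pad = mz_pad,
                 workers = as.integer(workers), seed = as.integer(seed)),
            class = "FitConfig")
}

# Robust baseline-noise estimate: scaled MAD of first differences, which is
# insensitive to the peak itself occupying part of the trace.
estimate_noise_sd <- function(y) {
  if (length(y) < 3L) return(0)
  stats::mad(diff(y)) / sqrt(2)
}

#' Initial parameter guess from the EIC itself
#'
#' Location from the intensity argmax, baseline from the mean of the lowest
#' decile, sigma from the width at half apex (/ 2.355), clipped to
#' \[scan interval, rt span\]; tau and alpha start at small positive values.
#'
#' @param eic an `EIC` with at least 5 points and positive maximum.
#' @param model target model name.
#' @return a [shape_params()] object.
#' @export
guess_initial <- function(eic, model = "emg") {
  t <- eic$rt; y <- eic$intensity
  if (length(t) < 5L)
    stop("EIC has fewer than 5 points; cannot initialize a fit",
         call. = FALSE)
  if (max(y) <= 0)
    stop("EIC carries no signal (all intensities zero)", call. = FALSE)
  n <- length(y)
  baseline <- mean(sort(y)[seq_len(max(1L, floor(n / 10)))])
  imax <- which.max(y)
  mu <- t[imax]
  amp <- max(y[imax] - baseline, .Machine$double.eps)
  half <- baseline + amp / 2
  scan_int <- stats::median(diff(t))
  span <- t[n] - t[1]

  # half-height crossings, linearly interpolated between bracketing scans
  below_l <- which(y[seq_len(imax)] < half)
  t_l <- if (length(below_l)) {
    i <- max(below_l)
    t[i] + (half - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
  } else t[1]
  below_r <- which(y[imax:n] < half)
  t_r <- if (length(below_r)) {
    i <- imax + min(below_r) - 1L
    t[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  } else t[n]
  sigma <- min(max((t_r - t_l) / 2.355, scan_int), span)

  switch(model,
    gaussian = shape_params("gaussian", amp, mu, sigma, baseline = baseline),
    skewed_gaussian = shape_params("skewed_gaussian", amp, mu, sigma,
                                   alpha = 0.5, baseline = baseline),
    emg = shape_params("emg", amp, mu, sigma, tau = max(sigma / 5, scan_int / 5),
                       baseline = baseline),
    stop("unknown model '", model, "'", call. = FALSE))
}

params_to_vec <- function(p) {
  v <- c(amplitude = p$amplitude, mu = p$mu, sigma = p$sigma,
         baseline = p$baseline)
  if (p$model == "skewed_gaussian") v <- c(v, alpha = p$alpha)
  if (p$model == "emg") v <- c(v, tau = p$tau)
  v
}

vec_to_params <- function(v, model) {
  shape_params(model, amplitude = v[["amplitude"]], mu = v[["mu"]],
               sigma = v[["sigma"]], baseline = v[["baseline"]],
               alpha = if (model == "skewed_gaussian") v[["alpha"]] else NULL,
               tau = if (model == "emg") v[["tau"]] else NULL)
}

#' Fit a line-shape model to an EIC
#'
#' Bounded nonlinear least squares (L-BFGS-B) starting from
#' [guess_initial()].  Bounds: `mu` within the EIC rt range, `sigma` in
#' \[scan interval / 2, rt span\], `amplitude` in (0, 2 max intensity\].
#' Optimizer failure or a physical parameter pinned at its bound is recorded
#' as `converged = FALSE`, never raised.
#'
#' @param eic an `EIC` with >= 5 points.
#' @param model model name (default from `config$model`).
#' @param config a [fit_config()].
#' @return a `FitResult`: list with `params`, `converged`,
#'   `residual_rel_rmse`, `n_points`.
#' @export
fit_curve <- function(eic, model = config$model, config = fit_config()) {
  t <- eic$rt; y <- eic$intensity
  if (length(t) < 5L)
    stop("EIC has fewer than 5 points; cannot fit", call. = FALSE)
  init <- guess_initial(eic, model)
  ymax <- max(y)
  scan_int <- stats::median(diff(t))
  span <- t[length(t)] - t[1]

  # fit on intensities scaled to max 1 so optim sees O(1) parameters
  ys <- y / ymax
  sc <- function(v) { v[["amplitude"]] <- v[["amplitude"]] / ymax
                      v[["baseline"]] <- v[["baseline"]] / ymax; v }
  unsc <- function(v) { v[["amplitude"]] <- v[["amplitude"]] * ymax
                        v[["baseline"]] <- v[["baseline"]] * ymax; v }
  v0 <- sc(params_to_vec(init))
  lower <- c(amplitude = 1e-9, mu = t[1], sigma = scan_int / 2, baseline = 0)
  upper <- c(amplitude = 2, mu = t[length(t)], sigma = span, baseline = 1)
  if (model == "skewed_gaussian") {
    lower <- c(lower, alpha = -30); upper <- c(upper, alpha = 30)
  }
  if (model == "emg") {
    lower <- c(lower, tau = scan_int / 50); upper <- c(upper, tau = 2 * span)
  }
  v0 <- pmin(pmax(v0, lower), upper)

  obj <- function(v) {
    p <- try(vec_to_params(unsc(stats::setNames(v, names(v0))), model),
             silent = TRUE)
    if (inherits(p, "try-error")) return(1e12)
    r <- model_eval(p, t) / ymax - ys
    s <- sum(r * r)
    if (!is.finite(s)) 1e12 else s
  }
  run_optim <- function(par) try(
    stats::optim(par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 500L, factr = 1e4)),
    silent = TRUE)
  opt <- run_optim(v0)
  # L-BFGS-B occasionally stops with an abnormal line-search code at a good
  # minimum; a restart from the returned point clears it
  for (r in 1:2) {
    if (inherits(opt, "try-error") || opt$convergence == 0L) break
    nxt <- run_optim(opt$par)
    if (inherits(nxt, "try-error")) break
    opt <- nxt
  }
  if (inherits(opt, "try-error")) {
    return(structure(list(params = init, converged = FALSE,
                          residual_rel_rmse = Inf,
                          n_points = length(t)), class = "FitResult"))
  }
  vf <- stats::setNames(opt$par, names(v0))
  params <- vec_to_params(unsc(vf), model)

  at_bound <- function(nm, end) {
    width <- upper[[nm]] - lower[[nm]]
    abs(vf[[nm]] - end[[nm]]) < 1e-6 * width
  }
  pinned <- at_bound("mu", lower) || at_bound("mu", upper) ||
    at_bound("sigma", lower) || at_bound("sigma", upper) ||
    at_bound("amplitude", upper) ||
    (model == "emg" && at_bound("tau", upper)) ||
    (model == "skewed_gaussian" &&
       (at_bound("alpha", lower) || at_bound("alpha", upper)))
  converged <- opt$convergence == 0L && !pinned

  resid <- model_eval(params, t) - y
  apex_h <- max(ymax - params$baseline, .Machine$double.eps)
  structure(list(params = params, converged = converged,
                 residual_rel_rmse = sqrt(mean(resid^2)) / apex_h,
                 n_points = length(t)),
            class = "FitResult")
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Fallback data-point integration
#'
#' Trapezoidal integration of baseline-subtracted intensities over the points
#' inside `[rt_lo, rt_hi]`.  The baseline is the straight segment joining the
#' window-edge intensities; subtracted values are clipped at 0.
#'
#' @param eic an `EIC`.
#' @param rt_lo,rt_hi integration window in seconds.
#' @return list with `found`, `area`, `apex_rt`, `apex_height`, `apex_index`
#'   (index into the EIC grid).  `found = FALSE` when no EIC point lies in
#'   the window.
#' @export
fallback_area <- function(eic, rt_lo, rt_hi) {
  sel <- which(eic$rt >= rt_lo & eic$rt <= rt_hi)
  if (!length(sel))
    return(list(found = FALSE, area = NA_real_, apex_rt = NA_real_,
                apex_height = NA_real_, apex_index = NA_integer_))
  t <- eic$rt[sel]; y <- eic$intensity[sel]
  n <- length(t)
  base <- if (n == 1L) y else
    y[1] + (y[n] - y[1]) * (t - t[1]) / (t[n] - t[1])
  ysub <- pmax(y - base, 0)
  i <- which.max(ysub)
  list(found = TRUE, area = trapz(t, ysub), apex_rt = t[i],
       apex_height = ysub[i], apex_index = sel[i])
}

new_measurement <- function(cpd_id, sample_id, found = FALSE, area = NA_real_,
                            apex_rt = NA_real_, apex_height = NA_real_,
                            fwhm = NA_real_, tailing_factor = NA_real_,
                            rt_min_obs = NA_real_, rt_max_obs = NA_real_,
                            mz_obs = NA_real_, ppm_error = NA_real_,
                            fallback_used = FALSE, fit = NULL) {
  structure(list(cpd_id = cpd_id, sample_id = sample_id, found = found,
                 area = area, apex_rt = apex_rt, apex_height = apex_height,
                 fwhm = fwhm, tailing_factor = tailing_factor,
                 rt_min_obs = rt_min_obs, rt_max_obs = rt_max_obs,
                 mz_obs = mz_obs, ppm_error = ppm_error,
                 fallback_used = fallback_used, fit = fit),
            class = "PeakMeasurement")
}

eic_mz_at <- function(eic, rt) {
  if (!length(eic$rt)) return(NA_real_)
  eic$mz_weighted[which.min(abs(eic$rt - rt))]
}

#' Measure one peak in one ROI
#'
#' Tries the configured model (then `skewed_gaussian` if different), accepts
#' the fit when it converged with `residual_rel_rmse <= max_residual`, apex
#' inside the ROI rt window and FWHM no wider than the window; on acceptance
#' the area is the model integral over the 5%-height extent.  Otherwise the
#' trapezoidal fallback over the integration window (the FIR window when
#' supplied, else the ROI rt window) is used.  A peak is `found` when its
#' apex height reaches `min_height_k` times the estimated baseline noise sd.
#'
#' @param eic an `EIC` for this (sample, compound).
#' @param roi the matching ROI row.
#' @param config a [fit_config()].
#' @param fir optional fallback-integration window (list/row with
#'   rtMin/rtMax) used instead of the ROI window on the fallback path.
#' @return a `PeakMeasurement`.
#' @export
measure_peak <- function(eic, roi, config = fit_config(), fir = NULL) {
  blank <- new_measurement(roi$cpdID, eic$sample_id)
  if (isTRUE(eic$empty) || !length(eic$rt) || max(eic$intensity) <= 0)
    return(blank)

  noise_sd <- estimate_noise_sd(eic$intensity)
  min_height <- config$min_height_k * noise_sd

  accepted <- NULL; metrics <- NULL
  if (length(eic$rt) >= 5L) {
    models <- unique(c(config$model, "skewed_gaussian"))
    for (mdl in models) {
      fit <- try(fit_curve(eic, mdl, config), silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) next
      if (fit$residual_rel_rmse > config$max_residual) next
      m <- try(peak_metrics(fit), silent = TRUE)
      if (inherits(m, "try-error")) next
      if (m$apex_rt < roi$rtMin || m$apex_rt > roi$rtMax) next
      if (m$fwhm > (roi$rtMax - roi$rtMin)) next
      accepted <- fit; metrics <- m
      break
    }
  }

  if (!is.null(accepted)) {
    if (metrics$apex_height < min_height) return(blank)
    area <- model_area(accepted$params, metrics$rt_min_obs,
                       metrics$rt_max_obs)
    out <- new_measurement(roi$cpdID, eic$sample_id, found = TRUE,
                           area = area, apex_rt = metrics$apex_rt,
                           apex_height = metrics$apex_height,
                           fwhm = metrics$fwhm,
                           tailing_factor = metrics$tailing_factor,
                           rt_min_obs = metrics$rt_min_obs,
                           rt_max_obs = metrics$rt_max_obs,
                           fallback_used = FALSE, fit = accepted)
  } else {
    win <- if (!is.null(fir)) fir else roi
    fb <- fallback_area(eic, win$rtMin, win$rtMax)
    if (!fb$found || fb$apex_height < min_height || fb$apex_height <= 0)
      return(blank)
    ext <- fallback_extent(eic, fb)
    out <- new_measurement(roi$cpdID, eic$sample_id, found = TRUE,
                           area = fb$area, apex_rt = fb$apex_rt,
                           apex_height = fb$apex_height,
                           rt_min_obs = ext[1], rt_max_obs = ext[2],
                           fallback_used = TRUE, fit = NULL)
  }
  out$mz_obs <- eic_mz_at(eic, out$apex_rt)
  if (!is.na(roi$mz) && !is.na(out$mz_obs))
    out$ppm_error <- (out$mz_obs - roi$mz) / roi$mz * 1e6
  out
}

# 5%-of-apex extent on the raw data around the fallback apex; used so that
# refinement consensus still works for compounds integrated via fallback.
fallback_extent <- function(eic, fb) {
  t <- eic$rt; y <- eic$intensity
  i <- fb$apex_index
  thr <- fb$apex_height * 0.05
  base <- y[i] - fb$apex_height
  lo <- i; while (lo > 1L && (y[lo - 1L] - base) > thr) lo <- lo - 1L
  hi <- i; while (hi < length(t) && (y[hi + 1L] - base) > thr) hi <- hi + 1L
  c(t[lo], t[hi])
}
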