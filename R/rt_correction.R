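# Retention-time re-calibration from calibrant compounds.
#
# The mapping is fitted as expected = f(observed) — calibrants are measured
# in the new run's frame — by classic RANSAC: draw minimal subsets, fit
# exactly, count inliers within a residual threshold, keep the largest
# consensus (ties: lower inlier RMSE, then earlier iteration), then refit by
# least squares on the consensus inliers.  Target windows are corrected by
# the inverse mapping; the raw data are never resampled.

#' RANSAC configuration
#'
#' @param n_iter number of random minimal subsets (default 500).
#' @param threshold inlier residual threshold in seconds (default 5).
#' @param min_inlier_fraction minimum fraction of observations that must be
#'   inliers for the calibration to be accepted (default 0.5).
#' @param seed RNG seed making the fit reproducible.
#' @return a `RansacConfig` list.
#' @export
ransac_config <- function(n_iter = 500L, threshold = 5,
                          min_inlier_fraction = 0.5, seed = 42L) {
  stopifnot(n_iter >= 1, threshold > 0,
            min_inlier_fraction > 0, min_inlier_fraction <= 1)
  structure(list(n_iter = as.integer(n_iter), threshold = threshold,
                 min_inlier_fraction = min_inlier_fraction,
                 seed = as.integer(seed)), class = "RansacConfig")
}

rt_model_min_n <- function(kind, degree) {
  switch(kind, offset = 1L, linear = 2L, polynomial = degree + 1L)
}

# exact / least-squares polynomial fit of expected on observed
rt_poly_fit <- function(obs, expd, degree) {
  X <- stats::poly(obs, degree = degree, raw = TRUE, simple = TRUE)
  X <- cbind(1, X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(NULL)
  as.numeric(qr.coef(qr_x, expd))
}

rt_fit_coefs <- function(obs, expd, kind, degree) {
  switch(kind,
    offset = mean(expd - obs),
    linear = rt_poly_fit(obs, expd, 1L),
    polynomial = rt_poly_fit(obs, expd, degree))
}

rt_predict <- function(model, x) {
  switch(model$kind,
    offset = x + model$coefficients,
    drop(cbind(1, stats::poly(x, degree = length(model$coefficients) - 1L,
                              raw = TRUE, simple = TRUE)) %*%
           model$coefficients))
}

#' Fit a robust retention-time calibration model
#'
#' @param obs data frame with columns `cpd_id`, `expected_rt`,
#'   `observed_rt` (seconds, > 0); at least the minimal sample size for the
#'   chosen model kind (offset 1, linear 2, polynomial degree + 1).
#' @param kind `"linear"` (default), `"offset"` or `"polynomial"`.
#' @param degree polynomial degree (2 or 3; only for `kind =
#'   "polynomial"`).
#' @param config a [ransac_config()].
#' @return an `RtModel`: kind, degree, `coefficients`, logical
#'   `inlier_mask`, `inlier_threshold`, `seed`, and `obs_range` (the
#'   observed-rt range used for polynomial inversion).
#' @export
fit_rt_ransac <- function(obs, kind = c("linear", "offset", "polynomial"),
                          degree = 2L, config = ransac_config()) {
  kind <- match.arg(kind)
  if (kind == "polynomial" && !(degree %in% 2:3))
    stop("polynomial degree must be 2 or 3", call. = FALSE)
  if (kind != "polynomial") degree <- if (kind == "linear") 1L else 0L
  req <- c("cpd_id", "expected_rt", "observed_rt")
  if (!all(req %in% names(obs)))
    stop("observations need columns cpd_id, expected_rt, observed_rt",
         call. = FALSE)
  x <- obs$observed_rt; y <- obs$expected_rt
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (!all(keep))
    stop("expected_rt and observed_rt must be finite and > 0", call. = FALSE)
  n <- length(x)
  min_n <- rt_model_min_n(kind, degree)
  if (n < min_n)
    stop(sprintf("need at least %d calibrant observations for kind '%s'",
                 min_n, kind), call. = FALSE)

  candidate <- function(coefs) {
    m <- list(kind = kind, coefficients = coefs)
    r <- y - rt_predict(m, x)
    mask <- abs(r) <= config$threshold
    list(coefs = coefs, mask = mask, n_in = sum(mask),
         rmse = if (any(mask)) sqrt(mean(r[mask]^2)) else Inf)
  }

  best <- NULL
  with_seed(config$seed, {
    for (it in seq_len(config$n_iter)) {
      idx <- sample.int(n, min_n)
      coefs <- rt_fit_coefs(x[idx], y[idx], kind, degree)
      if (is.null(coefs) || any(!is.finite(coefs))) next
      cand <- candidate(coefs)
      if (is.null(best) || cand$n_in > best$n_in ||
          (cand$n_in == best$n_in && cand$rmse < best$rmse))
        best <- cand
    }
  })
  if (n == min_n && is.null(best))   # degenerate exact-fit fallback
    best <- candidate(rt_fit_coefs(x, y, kind, degree))

  need <- max(min_n, ceiling(config$min_inlier_fraction * n))
  if (is.null(best) || best$n_in < need)
    stop(sprintf(paste0(
      "retention-time calibration failed: best consensus has %d/%d inliers ",
      "(need >= %d at threshold %.3g s)"),
      if (is.null(best)) 0L else best$n_in, n, need, config$threshold),
      call. = FALSE)

  refit <- rt_fit_coefs(x[best$mask], y[best$mask], kind, degree)
  if (is.null(refit)) refit <- best$coefs
  final <- candidate(refit)
  structure(list(kind = kind, degree = degree, coefficients = refit,
                 inlier_mask = final$mask, inlier_threshold = config$threshold,
                 seed = config$seed, obs_range = range(x)),
            class = "RtModel")
}

#' @export
print.RtModel <- function(x, ...) {
  cat(sprintf("RtModel (%s): coefficients [%s], %d/%d inliers at %.3g s\n",
              x$kind, paste(signif(x$coefficients, 6), collapse = ", "),
              sum(x$inlier_mask), length(x$inlier_mask),
              x$inlier_threshold))
  invisible(x)
}

rt_invert <- function(model, y) {
  switch(model$kind,
    offset = y - model$coefficients,
    linear = {
      b <- model$coefficients[2]
      if (abs(b) < 1e-12)
        stop("linear rt model has near-zero slope; cannot invert",
             call. = FALSE)
      (y - model$coefficients[1]) / b
    },
    polynomial = {
      span <- diff(model$obs_range)
      lo <- model$obs_range[1] - span - 1
      hi <- model$obs_range[2] + span + 1
      grid <- seq(lo, hi, length.out = 512L)
      fg <- rt_predict(model, grid)
      if (any(diff(fg) <= 0))
        stop(paste0("polynomial rt model is not monotone increasing on the ",
                    "run's rt range; use a lower degree"), call. = FALSE)
      vapply(y, function(yy) {
        if (yy < fg[1] || yy > fg[length(fg)])
          stop("rt value outside invertible range of the calibration model",
               call. = FALSE)
        stats::uniroot(function(t) rt_predict(model, t) - yy,
                       lower = lo, upper = hi, tol = 1e-10)$root
      }, numeric(1))
    })
}

#' Correct ROI windows with a retention-time model
#'
#' Maps each ROI's expected-rt frame into the observed frame of the new run
#' by applying the inverse calibration `f^{-1}` to rtMin / rt / rtMax
#' (closed form for offset and linear models, monotone numerical inversion
#' for polynomials).  m/z boundaries are untouched and window ordering is
#' preserved.
#'
#' @param rois an `ROISet`.
#' @param model an `RtModel` from [fit_rt_ransac()].
#' @return the corrected `ROISet`.
#' @export
apply_rt_model <- function(rois, model) {
  validate_roiset(rois)
  out <- as.data.frame(rois)
  if (model$kind == "linear" && model$coefficients[2] <= 0)
    stop("rt calibration has non-positive slope; physically meaningless",
         call. = FALSE)
  for (cc in c("rtMin", "rt", "rtMax")) {
    v <- out[[cc]]
    ok <- !is.na(v)
    v[ok] <- rt_invert(model, v[ok])
    out[[cc]] <- v
  }
  if (any(out$rtMin >= out$rtMax))
    stop("rt correction produced an inverted window; check the model",
         call. = FALSE)
  as_roiset(out, source_path = attr(rois, "source_path"))
}

#' Assemble calibrant observations from a table and/or prior results
#'
#' When the calibrant table lacks `observed_rt`, the observed value for each
#' calibrant compound is taken from a prior annotation as the median apex rt
#' across samples.
#'
#' @param calibrants data frame from [read_calibrant_csv()].
#' @param state optional `AnnotationState` supplying observed apex rts.
#' @return data frame with cpd_id, expected_rt, observed_rt.
#' @export
calibrant_observations <- function(calibrants, state = NULL) {
  if (!is.null(calibrants$observed_rt) &&
      all(is.finite(calibrants$observed_rt)))
    return(calibrants[, c("cpd_id", "expected_rt", "observed_rt")])
  if (is.null(state))
    stop(paste0("calibrant table has no observedRt column; supply a prior ",
                "annotation state to derive observed apex rts"),
         call. = FALSE)
  apex <- annotation_matrix(state, "apex_rt")
  obs_rt <- vapply(calibrants$cpd_id, function(id) {
    if (!id %in% colnames(apex)) return(NA_real_)
    stats::median(apex[, id], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(cpd_id = calibrants$cpd_id,
                    expected_rt = calibrants$expected_rt,
                    observed_rt = obs_rt, stringsAsFactors = FALSE)
  out <- out[is.finite(out$observed_rt), , drop = FALSE]
  if (!nrow(out))
    stop("no calibrant compound has an observed apex rt", call. = FALSE)
  out
}
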