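# Dataset-level orchestration: run extraction + fitting over all samples x
# compounds, summarize, and propose consensus-refined windows (uROI) and
# fallback integration regions (FIR) for a second pass.
#
# Per-file work is independent and free of RNG, so the result is identical
# for any worker count; failed files are recorded as an all-not-found row
# with an error note instead of aborting the batch.

annotate_one_file <- function(path, rois, config, firs = NULL) {
  run <- tryCatch(read_mzml(path), error = function(e) e)
  sid <- sub("\\.(mzML|mzml)(\\.gz)?$", "", basename(path))
  if (inherits(run, "error")) {
    meas <- lapply(seq_len(nrow(rois)), function(i)
      new_measurement(rois$cpdID[i], sid))
    return(list(sample_id = sid, measurements = meas,
                error = conditionMessage(run)))
  }
  eics <- extract_all(run, rois)
  meas <- lapply(seq_len(nrow(rois)), function(i)
    measure_peak(eics[[i]], rois[i, ], config,
                 fir = if (!is.null(firs)) firs[i, ] else NULL))
  list(sample_id = run$sample_id, measurements = meas, error = NA_character_)
}

#' Annotate a batch of raw files against an ROI set
#'
#' Runs [extract_eic()] + [measure_peak()] for every (sample, compound)
#' pair.  With `use_uroi = TRUE` the refined windows in `u_rois` drive the
#' extraction; with `use_fir = TRUE` the `firs` windows drive the fallback
#' integration.  Output is bit-identical for any `config$workers` value.
#'
#' @param files character vector of mzML paths (>= 1).
#' @param rois an `ROISet`.
#' @param config a [fit_config()].
#' @param u_rois,firs optional refined-ROI / fallback-window sets (same
#'   cpdIDs as `rois`).
#' @param use_uroi,use_fir switches applying `u_rois` / `firs`.
#' @return an `AnnotationState`.
#' @export
run_annotation <- function(files, rois, config = fit_config(),
                           u_rois = NULL, firs = NULL,
                           use_uroi = FALSE, use_fir = FALSE) {
  if (!length(files)) stop("no input files given", call. = FALSE)
  validate_roiset(rois)
  for (set in list(u_rois, firs))
    if (!is.null(set) && !identical(set$cpdID, rois$cpdID))
      stop("u_rois/firs must carry the same cpdIDs as rois, in order",
           call. = FALSE)
  active <- if (use_uroi && !is.null(u_rois)) u_rois else rois
  active_fir <- if (use_fir && !is.null(firs)) firs else NULL

  worker <- function(path) annotate_one_file(path, active, config, active_fir)
  res <- if (config$workers > 1L)
    parallel::mclapply(files, worker, mc.cores = config$workers)
  else lapply(files, worker)

  errs <- vapply(res, `[[`, character(1), "error")
  if (all(!is.na(errs)))
    stop("all input files failed:\n",
         paste(sprintf("  %s: %s", basename(files), errs), collapse = "\n"),
         call. = FALSE)

  structure(list(
    sample_ids = vapply(res, `[[`, character(1), "sample_id"),
    rois = rois, u_rois = u_rois, firs = firs,
    use_uroi = use_uroi, use_fir = use_fir,
    measurements = lapply(res, `[[`, "measurements"),
    errors = stats::setNames(errs, vapply(res, `[[`, character(1),
                                          "sample_id")),
    config = config), class = "AnnotationState")
}

#' @export
print.AnnotationState <- function(x, ...) {
  nf <- sum(vapply(x$measurements, function(row)
    sum(vapply(row, `[[`, logical(1), "found")), numeric(1)))
  cat(sprintf(
    "AnnotationState: %d samples x %d compounds, %d peaks found%s\n",
    length(x$sample_ids), nrow(x$rois), nf,
    if (any(!is.na(x$errors)))
      sprintf(" (%d failed files)", sum(!is.na(x$errors))) else ""))
  invisible(x)
}

#' Extract one measurement field as a samples x compounds matrix
#'
#' @param state an `AnnotationState`.
#' @param field a `PeakMeasurement` field name (e.g. `"area"`,
#'   `"apex_rt"`, `"found"`).
#' @return matrix with sample-id rownames and cpdID colnames.
#' @export
annotation_matrix <- function(state, field) {
  ns <- length(state$sample_ids); nc <- nrow(state$rois)
  vals <- matrix(NA_real_, ns, nc,
                 dimnames = list(state$sample_ids, state$rois$cpdID))
  for (s in seq_len(ns))
    for (i in seq_len(nc)) {
      v <- state$measurements[[s]][[i]][[field]]
      vals[s, i] <- if (is.logical(v)) as.numeric(v) else v
    }
  vals
}

#' Per-compound dataset summary
#'
#' Statistics over found measurements only: fraction found, median/IQR of
#' apex-rt deviation from the expected rt, relative sd of the area (%),
#' fraction integrated via fallback, and median m/z error in ppm.
#'
#' @param state an `AnnotationState`.
#' @return data frame, one row per compound.
#' @export
summarize_annotation <- function(state) {
  n_samp <- length(state$sample_ids)
  out <- lapply(seq_len(nrow(state$rois)), function(i) {
    roi <- state$rois[i, ]
    ms <- lapply(state$measurements, `[[`, i)
    found <- vapply(ms, `[[`, logical(1), "found")
    fm <- ms[found]
    g <- function(f) vapply(fm, `[[`, numeric(1), f)
    rt_dev <- if (length(fm) && !is.na(roi$rt)) g("apex_rt") - roi$rt else
      numeric(0)
    areas <- if (length(fm)) g("area") else numeric(0)
    data.frame(
      cpd_id = roi$cpdID,
      found_fraction = mean(found),
      rt_dev_median = if (length(rt_dev)) stats::median(rt_dev) else NA_real_,
      rt_dev_iqr = if (length(rt_dev)) stats::IQR(rt_dev) else NA_real_,
      area_rsd = if (length(areas) > 1L && mean(areas) > 0)
        stats::sd(areas) / mean(areas) * 100 else
          if (length(areas)) 0 else NA_real_,
      fallback_fraction = if (length(fm))
        mean(vapply(fm, `[[`, logical(1), "fallback_used")) else NA_real_,
      ppm_error_median = if (length(fm))
        stats::median(g("ppm_error"), na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Propose consensus-refined windows for a second pass
#'
#' For each compound found in at least `config$min_found` samples, the
#' refined ROI (uROI) rt window spans the observed 5%-height extents padded
#' by one median FWHM (or `config$rt_pad`), its m/z window is the observed
#' m/z range padded by `config$mz_pad` but never wider than the original,
#' and its expected rt is the median apex rt.  The fallback integration
#' region (FIR) rt window is the median observed extent; its m/z window is
#' the uROI one.  Compounds below the threshold keep their original ROI and
#' are flagged `refined = FALSE`.
#'
#' @param state an `AnnotationState` from a completed run.
#' @param config a [fit_config()].
#' @return list with `u_rois` and `firs`, both `ROISet`s with an extra
#'   logical column `refined`.
#' @export
propose_refinement <- function(state, config = state$config) {
  uroi <- as.data.frame(state$rois)
  fir <- as.data.frame(state$rois)
  uroi$refined <- FALSE
  fir$refined <- FALSE
  for (i in seq_len(nrow(state$rois))) {
    roi <- state$rois[i, ]
    fm <- Filter(function(m) isTRUE(m$found),
                 lapply(state$measurements, `[[`, i))
    if (length(fm) < config$min_found) next
    g <- function(f) vapply(fm, `[[`, numeric(1), f)
    ext_lo <- g("rt_min_obs"); ext_hi <- g("rt_max_obs")
    apexes <- g("apex_rt")
    pad <- config$rt_pad
    if (is.null(pad)) {
      fw <- g("fwhm")
      pad <- if (all(is.na(fw))) stats::median(ext_hi - ext_lo) / 2 else
        stats::median(fw, na.rm = TRUE)
    }
    rt_lo <- min(ext_lo) - pad
    rt_hi <- max(ext_hi) + pad
    mzs <- g("mz_obs")
    if (all(is.na(mzs))) {
      mz_lo <- roi$mzMin; mz_hi <- roi$mzMax; mz_c <- roi$mz
    } else {
      mz_lo <- max(min(mzs, na.rm = TRUE) - config$mz_pad, roi$mzMin)
      mz_hi <- min(max(mzs, na.rm = TRUE) + config$mz_pad, roi$mzMax)
      mz_c <- min(max(stats::median(mzs, na.rm = TRUE), mz_lo), mz_hi)
    }
    rt_c <- stats::median(apexes)
    uroi[i, c("rtMin", "rt", "rtMax")] <-
      c(rt_lo, min(max(rt_c, rt_lo), rt_hi), rt_hi)
    uroi[i, c("mzMin", "mz", "mzMax")] <- c(mz_lo, mz_c, mz_hi)
    uroi$refined[i] <- TRUE
    f_lo <- stats::median(ext_lo); f_hi <- stats::median(ext_hi)
    fir[i, c("rtMin", "rt", "rtMax")] <-
      c(f_lo, min(max(rt_c, f_lo), f_hi), f_hi)
    fir[i, c("mzMin", "mz", "mzMax")] <- c(mz_lo, mz_c, mz_hi)
    fir$refined[i] <- TRUE
  }
  list(u_rois = as_roiset(uroi, source_path = "refined"),
       firs = as_roiset(fir, source_path = "refined"))
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (cc in setdiff(names(df), "sample_id"))
    df[[cc]] <- vapply(df[[cc]], function(x)
      if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE),
      character(1))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Export the annotation state as CSV tables
#'
#' Writes samples x compounds matrices (area, apex_rt, apex_height, fwhm,
#' tailing_factor, rt_min_obs, rt_max_obs, mz_obs, found, fallback), the
#' compound summary, the active ROI set, and — when present — the uROI and
#' FIR sets.  Missing measurements become empty cells, never zeros.
#'
#' @param state an `AnnotationState`.
#' @param dir output directory (created if absent).
#' @return named character vector of the files written.
#' @export
export_tables <- function(state, dir) {
  ok <- tryCatch({ dir.create(dir, showWarnings = FALSE, recursive = TRUE)
                   file.access(dir, 2) == 0 }, error = function(e) FALSE)
  if (!isTRUE(ok))
    stop(sprintf("cannot write into directory '%s'", dir), call. = FALSE)
  fields <- c("area", "apex_rt", "apex_height", "fwhm", "tailing_factor",
              "rt_min_obs", "rt_max_obs", "mz_obs", "found", "fallback_used")
  fnames <- c(area = "area", apex_rt = "apex_rt", apex_height = "apex_height",
              fwhm = "fwhm", tailing_factor = "tailing_factor",
              rt_min_obs = "rt_min_obs", rt_max_obs = "rt_max_obs",
              mz_obs = "mz_obs", found = "found",
              fallback_used = "fallback")
  paths <- character(0)
  for (f in fields) {
    p <- file.path(dir, paste0(fnames[[f]], ".csv"))
    write_matrix_csv(annotation_matrix(state, f), p)
    paths[fnames[[f]]] <- p
  }
  p <- file.path(dir, "compound_summary.csv")
  utils::write.csv(summarize_annotation(state), p, row.names = FALSE, na = "")
  paths["compound_summary"] <- p
  paths["roi"] <- write_roi_csv(state$rois, file.path(dir, "roi_used.csv"))
  if (!is.null(state$u_rois))
    paths["uroi"] <- write_roi_csv(state$u_rois, file.path(dir, "uroi.csv"))
  if (!is.null(state$firs))
    paths["fir"] <- write_roi_csv(state$firs, file.path(dir, "fir.csv"))
  paths
}
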