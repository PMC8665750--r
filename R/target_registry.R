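# ROI target files and calibrant tables.
#
# The target file is a plain CSV whose column names follow the convention
# widely used for targeted LC-MS integration (cpdID, cpdName, rtMin, rt,
# rtMax, mzMin, mz, mzMax).  rt columns are seconds; no minute auto-detection
# is performed (the CLI exposes an explicit --rt-unit override instead).
# Extra columns are carried along untouched.

roi_required_cols <- c("cpdID", "cpdName", "rtMin", "rtMax", "mzMin", "mzMax")
roi_numeric_cols  <- c("rtMin", "rt", "rtMax", "mzMin", "mz", "mzMax")

#' Build an ROI set from a data frame
#'
#' @param df data frame with at least cpdID, cpdName, rtMin, rtMax, mzMin,
#'   mzMax; optional rt / mz (expected apex position); extra columns kept.
#' @param source_path optional provenance string.
#' @return a validated `ROISet` (a data frame).
#' @export
as_roiset <- function(df, source_path = NA_character_) {
  missing_cols <- setdiff(roi_required_cols, names(df))
  if (length(missing_cols))
    stop("ROI table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  if (!"mz" %in% names(df)) df$mz <- NA_real_
  for (cc in roi_numeric_cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df$cpdID <- as.character(df$cpdID)
  df$cpdName <- as.character(df$cpdName)
  canonical <- c("cpdID", "cpdName", "rtMin", "rt", "rtMax",
                 "mzMin", "mz", "mzMax")
  df <- df[, c(canonical, setdiff(names(df), canonical)), drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("ROISet", "data.frame"),
                   source_path = source_path)
  validate_roiset(out)
  out
}

validate_roiset <- function(rois) {
  if (nrow(rois) == 0L) stop("ROI set must be non-empty", call. = FALSE)
  dup <- rois$cpdID[duplicated(rois$cpdID)]
  if (length(dup))
    stop("duplicated cpdID in ROI set: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- function(id, field, msg)
    stop(sprintf("invalid ROI for cpdID '%s': %s (%s)", id, msg, field),
         call. = FALSE)
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    for (cc in roi_required_cols[-(1:2)])
      if (!is.finite(r[[cc]])) bad(r$cpdID, cc, "must be a finite number")
    if (r$rtMin >= r$rtMax) bad(r$cpdID, "rtMin/rtMax", "rtMin must be < rtMax")
    if (r$mzMin >= r$mzMax) bad(r$cpdID, "mzMin/mzMax", "mzMin must be < mzMax")
    if (!is.na(r$rt) && (r$rt < r$rtMin || r$rt > r$rtMax))
      bad(r$cpdID, "rt", "expected rt must lie within [rtMin, rtMax]")
    if (!is.na(r$mz) && (r$mz < r$mzMin || r$mz > r$mzMax))
      bad(r$cpdID, "mz", "expected mz must lie within [mzMin, mzMax]")
  }
  invisible(rois)
}

#' Read a compound ROI target CSV
#'
#' @param path CSV file with header columns cpdID, cpdName, rtMin, rtMax,
#'   mzMin, mzMax (required) and rt, mz (optional).  rt values are seconds.
#' @return an `ROISet`.
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read ROI file '%s': no such file", path),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_roiset(df, source_path = path)
}

#' Write an ROI set to CSV
#'
#' Round-trips losslessly through [read_roi_csv()]: absent optional fields
#' become empty cells and numeric values are written with full precision.
#'
#' @param rois an `ROISet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  validate_roiset(rois)
  df <- as.data.frame(rois)
  for (cc in names(df))
    if (is.numeric(df[[cc]]))
      df[[cc]] <- vapply(df[[cc]], function(x)
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE),
        character(1))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write ROI file '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read a calibrant table CSV
#'
#' Columns: cpdID, expectedRt (seconds), optional observedRt.  When an
#' `ROISet` is supplied, every calibrant cpdID must exist in it.
#'
#' @param path CSV path.
#' @param rois optional companion `ROISet` for cross-validation.
#' @return data frame with columns cpd_id, expected_rt and (optionally)
#'   observed_rt.
#' @export
read_calibrant_csv <- function(path, rois = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read calibrant file '%s': no such file", path),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("cpdID", "expectedRt"), names(df))
  if (length(missing_cols))
    stop("calibrant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(cpd_id = as.character(df$cpdID),
                    expected_rt = as.numeric(df$expectedRt),
                    stringsAsFactors = FALSE)
  if ("observedRt" %in% names(df))
    out$observed_rt <- as.numeric(df$observedRt)
  if (any(!is.finite(out$expected_rt)) || any(out$expected_rt <= 0))
    stop("calibrant expectedRt values must be finite and > 0", call. = FALSE)
  if (!is.null(rois)) {
    unknown <- setdiff(out$cpd_id, rois$cpdID)
    if (length(unknown))
      stop("calibrant cpdID(s) absent from ROI set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}
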