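# mzML reading and ROI-bounded chromatogram extraction.
#
# Only the mzML subset needed for targeted MS1 work is handled: MS1 spectra,
# 32/64-bit little-endian binary arrays, plain or zlib-compressed, retention
# time in seconds or minutes (converted on read).  Profile-mode spectra pass
# through untouched; summing over the m/z window at extraction time absorbs
# the profile points, so no centroiding step is needed.

#' Construct a single mass spectrum
#'
#' @param scan_index 0-based scan index.
#' @param rt retention time in seconds.
#' @param mz ascending m/z vector (Da).
#' @param intensity non-negative intensity vector, same length as `mz`.
#' @param ms_level MS level (1 for survey scans).
#' @param centroided logical centroid-mode flag.
#' @return an object of class `Spectrum`.
#' @export
ms_spectrum <- function(scan_index, rt, mz, intensity, ms_level = 1L,
                     centroided = TRUE) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("mz values must be strictly ascending", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  structure(list(scan_index = as.integer(scan_index), rt = rt,
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 ms_level = as.integer(ms_level),
                 centroided = isTRUE(centroided)),
            class = "Spectrum")
}

#' Construct a raw run
#'
#' @param sample_id sample identifier.
#' @param spectra list of [ms_spectrum()] objects, ordered by rt.
#' @param polarity `"positive"`, `"negative"` or `"unknown"`.
#' @return an object of class `RawRun`.
#' @export
raw_run <- function(sample_id, spectra,
                    polarity = c("unknown", "positive", "negative")) {
  polarity <- match.arg(polarity)
  ms1 <- vapply(spectra, function(s) s$ms_level == 1L, logical(1))
  if (!any(ms1)) stop("run contains no MS1 spectra", call. = FALSE)
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) spectra <- spectra[order(rts)]
  structure(list(sample_id = sample_id, spectra = spectra,
                 polarity = polarity),
            class = "RawRun")
}

#' @export
print.RawRun <- function(x, ...) {
  rts <- vapply(x$spectra, `[[`, numeric(1), "rt")
  cat(sprintf("RawRun '%s': %d MS1 spectra, rt %.2f-%.2f s, polarity %s\n",
              x$sample_id, length(x$spectra), min(rts), max(rts),
              x$polarity))
  invisible(x)
}

decode_binary_array <- function(b64_text, precision_bytes, zlib, n_expected) {
  raw_bytes <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64_text))
  if (zlib) raw_bytes <- memDecompress(raw_bytes, type = "gzip")
  readBin(raw_bytes, what = "double", n = n_expected,
          size = precision_bytes, endian = "little")
}

cv_accessions <- function(node) {
  xml2::xml_attr(xml2::xml_find_all(node, "./cvParam"), "accession")
}

parse_mzml_spectrum <- function(node, default_centroided) {
  acc <- cv_accessions(node)
  ms_level_node <- xml2::xml_find_first(
    node, "./cvParam[@accession='MS:1000511']")
  ms_level <- if (inherits(ms_level_node, "xml_missing")) 1L else
    as.integer(xml2::xml_attr(ms_level_node, "value"))
  centroided <- if ("MS:1000127" %in% acc) TRUE
    else if ("MS:1000128" %in% acc) FALSE else default_centroided
  polarity <- if ("MS:1000130" %in% acc) "positive"
    else if ("MS:1000129" %in% acc) "negative" else "unknown"

  rt_node <- xml2::xml_find_first(
    node, ".//scan/cvParam[@accession='MS:1000016']")
  if (inherits(rt_node, "xml_missing"))
    stop("spectrum without scan start time", call. = FALSE)
  rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
  unit <- xml2::xml_attr(rt_node, "unitAccession")
  unit_name <- xml2::xml_attr(rt_node, "unitName")
  if (identical(unit, "UO:0000031") || identical(unit_name, "minute"))
    rt <- rt * 60

  n <- as.integer(xml2::xml_attr(node, "defaultArrayLength"))
  mz <- numeric(0); inten <- numeric(0)
  for (bda in xml2::xml_find_all(node, ".//binaryDataArray")) {
    bacc <- cv_accessions(bda)
    bytes <- if ("MS:1000521" %in% bacc) 4L else 8L
    zlib <- "MS:1000574" %in% bacc
    txt <- xml2::xml_text(xml2::xml_find_first(bda, "./binary"))
    vals <- if (n > 0L) decode_binary_array(txt, bytes, zlib, n) else numeric(0)
    if ("MS:1000514" %in% bacc) mz <- vals
    else if ("MS:1000515" %in% bacc) inten <- vals
  }
  if (length(mz) != length(inten))
    stop("m/z and intensity arrays differ in length", call. = FALSE)
  list(rt = rt, mz = mz, intensity = inten, ms_level = ms_level,
       centroided = centroided, polarity = polarity)
}

#' Read an mzML file into a `RawRun`
#'
#' Keeps MS1 spectra only, ordered by retention time.  Handles plain or
#' gzipped mzML, 32/64-bit float arrays, zlib or no compression, and rt in
#' seconds or minutes (minutes are converted).  The centroid flag is taken
#' from the file when present, otherwise assumed `TRUE`.
#'
#' @param path mzML file path.
#' @return a [raw_run()] object.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read mzML file '%s': no such file", path),
         call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse mzML file '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  xml2::xml_ns_strip(doc)

  file_acc <- cv_accessions(
    xml2::xml_find_first(doc, ".//fileDescription/fileContent"))
  default_centroided <- !("MS:1000128" %in% file_acc)

  run_node <- xml2::xml_find_first(doc, ".//run")
  sample_id <- if (!inherits(run_node, "xml_missing"))
    xml2::xml_attr(run_node, "id") else NA_character_
  if (is.na(sample_id) || !nzchar(sample_id))
    sample_id <- sub("\\.(mzML|mzml)(\\.gz)?$", "", basename(path))

  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  parsed <- lapply(nodes, parse_mzml_spectrum, default_centroided)
  parsed <- Filter(function(s) s$ms_level == 1L, parsed)
  if (!length(parsed))
    stop(sprintf("mzML file '%s' contains no MS1 spectra", path),
         call. = FALSE)

  pol <- unique(vapply(parsed, `[[`, character(1), "polarity"))
  pol <- setdiff(pol, "unknown")
  polarity <- if (length(pol) == 1L) pol else "unknown"

  parsed <- parsed[order(vapply(parsed, `[[`, numeric(1), "rt"))]
  spectra <- lapply(seq_along(parsed), function(i) {
    s <- parsed[[i]]
    ms_spectrum(i - 1L, s$rt, s$mz, s$intensity, s$ms_level, s$centroided)
  })
  raw_run(sample_id, spectra, polarity)
}

#' Extract an ion chromatogram for one ROI
#'
#' One point per MS1 scan whose rt falls in the closed interval
#' `[rtMin, rtMax]`; each point is the SUM of intensities of all ions with
#' m/z inside the closed `[mzMin, mzMax]` window (scans with no matching
#' ions contribute 0, so the rt grid is always the scan grid).  The
#' intensity-weighted mean m/z per scan is carried along for downstream
#' mass-accuracy metrics.
#'
#' @param run a [raw_run()] object.
#' @param roi one row of an `ROISet` (or any list with rtMin/rtMax/
#'   mzMin/mzMax and cpdID fields).
#' @return an object of class `EIC` with fields `sample_id`, `cpd_id`, `rt`,
#'   `intensity`, `mz_weighted`, `n_scans` and an `empty` flag when no scan
#'   falls inside the rt window.
#' @export
extract_eic <- function(run, roi) {
  rts <- vapply(run$spectra, `[[`, numeric(1), "rt")
  keep <- which(rts >= roi$rtMin & rts <= roi$rtMax)
  if (!length(keep)) {
    return(structure(list(sample_id = run$sample_id, cpd_id = roi$cpdID,
                          rt = numeric(0), intensity = numeric(0),
                          mz_weighted = numeric(0), n_scans = 0L,
                          empty = TRUE),
                     class = "EIC"))
  }
  n <- length(keep)
  inten <- numeric(n); mzw <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    s <- run$spectra[[keep[j]]]
    sel <- s$mz >= roi$mzMin & s$mz <= roi$mzMax
    if (any(sel)) {
      ii <- s$intensity[sel]
      inten[j] <- sum(ii)
      if (inten[j] > 0) mzw[j] <- sum(s$mz[sel] * ii) / inten[j]
    }
  }
  structure(list(sample_id = run$sample_id, cpd_id = roi$cpdID,
                 rt = rts[keep], intensity = inten, mz_weighted = mzw,
                 n_scans = n, empty = FALSE),
            class = "EIC")
}

#' Extract chromatograms for every ROI in a set
#'
#' Single pass over the ROI set; element order matches the ROI order and
#' each element is identical to the corresponding [extract_eic()] call.
#'
#' @param run a [raw_run()] object.
#' @param rois an `ROISet`.
#' @return list of `EIC` objects, one per ROI.
#' @export
extract_all <- function(run, rois) {
  validate_roiset(rois)
  lapply(seq_len(nrow(rois)), function(i) extract_eic(run, rois[i, ]))
}
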