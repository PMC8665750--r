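# Synthetic LC-MS run generator with a full ground-truth ledger.
#
# Each simulated run is a grid of MS1 scans; every planted compound
# contributes one centroid per scan at its m/z (plus Gaussian jitter) whose
# intensity follows a Gaussian (tau = 0) or EMG (tau > 0) line shape
# evaluated at the scan time, on top of a constant baseline and additive
# Gaussian noise clipped at zero.  The ledger records, per peak, the drifted
# apex rt (located numerically) and the true area (quadrature at generation
# time), so downstream modules can be checked against known truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe one planted peak
#'
#' @param cpd_id compound identifier.
#' @param mz centroid m/z in Da.
#' @param mu Gaussian location in seconds.
#' @param sigma Gaussian spread in seconds (> 0).
#' @param tau EMG exponential time constant in seconds; 0 = pure Gaussian.
#' @param amplitude peak amplitude (intensity units).
#' @return a `PeakSpec` list; `true_area` is filled in by [simulate_run()].
#' @export
peak_spec <- function(cpd_id, mz, mu, sigma, tau = 0, amplitude = 1e5) {
  stopifnot(sigma > 0, amplitude > 0, tau >= 0)
  structure(list(cpd_id = as.character(cpd_id), mz = mz, mu = mu,
                 sigma = sigma, tau = tau, amplitude = amplitude),
            class = "PeakSpec")
}

peak_shape <- function(spec, mu = spec$mu) {
  if (spec$tau > 0)
    shape_params("emg", spec$amplitude, mu, spec$sigma, tau = spec$tau)
  else
    shape_params("gaussian", spec$amplitude, mu, spec$sigma)
}

#' Describe one synthetic run
#'
#' @param peaks list of [peak_spec()] objects.
#' @param n_scans number of MS1 scans (>= 10).
#' @param rt_start first scan time in seconds.
#' @param scan_interval scan spacing in seconds (> 0).
#' @param noise_sd sd of additive Gaussian intensity noise.
#' @param baseline constant baseline intensity.
#' @param mz_jitter_sd sd of per-scan centroid m/z jitter (Da).
#' @param rt_drift drift applied to every peak location: `list(kind =
#'   "none")`, `list(kind = "offset", delta = )` or
#'   `list(kind = "linear", a = , b = )` mapping mu to `a + b * mu`.
#' @param seed integer RNG seed; the run is fully determined by it.
#' @param sample_id sample identifier.
#' @return a `RunRecipe` list.
#' @export
run_recipe <- function(peaks, n_scans = 600L, rt_start = 0,
                       scan_interval = 1, noise_sd = 0, baseline = 0,
                       mz_jitter_sd = 0, rt_drift = list(kind = "none"),
                       seed = 1L, sample_id = "synthetic") {
  stopifnot(n_scans >= 10L, scan_interval > 0, noise_sd >= 0, baseline >= 0,
            mz_jitter_sd >= 0)
  if (!rt_drift$kind %in% c("none", "offset", "linear"))
    stop("rt_drift kind must be none, offset or linear", call. = FALSE)
  structure(list(peaks = peaks, n_scans = as.integer(n_scans),
                 rt_start = rt_start, scan_interval = scan_interval,
                 noise_sd = noise_sd, baseline = baseline,
                 mz_jitter_sd = mz_jitter_sd, rt_drift = rt_drift,
                 seed = as.integer(seed), sample_id = sample_id),
            class = "RunRecipe")
}

drift_mu <- function(mu, drift) {
  switch(drift$kind,
         none = mu,
         offset = mu + drift$delta,
         linear = drift$a + drift$b * mu)
}

#' Simulate one raw run with known ground truth
#'
#' @param recipe a [run_recipe()].
#' @return list with `run` (a [raw_run()]) and `truth`, a data frame with
#'   one row per planted peak: cpd_id, mz, mu (drifted), sigma, tau,
#'   amplitude, apex_rt (drifted, located numerically) and true_area
#'   (full-support quadrature of the noiseless shape).
#' @export
simulate_run <- function(recipe) {
  np <- length(recipe$peaks)
  times <- recipe$rt_start + (seq_len(recipe$n_scans) - 1L) * recipe$scan_interval

  shapes <- vector("list", np)
  truth <- data.frame(cpd_id = character(np), mz = numeric(np),
                      mu = numeric(np), sigma = numeric(np),
                      tau = numeric(np), amplitude = numeric(np),
                      apex_rt = numeric(np), true_area = numeric(np),
                      stringsAsFactors = FALSE)
  for (k in seq_len(np)) {
    sp <- recipe$peaks[[k]]
    mu_d <- drift_mu(sp$mu, recipe$rt_drift)
    shapes[[k]] <- peak_shape(sp, mu_d)
    apex <- shape_apex(shapes[[k]])
    area <- stats::integrate(function(t) model_eval(shapes[[k]], t),
                             mu_d - 60 * sp$sigma,
                             mu_d + 60 * sp$sigma + 60 * max(sp$tau, sp$sigma),
                             rel.tol = 1e-10, subdivisions = 2000L)$value
    truth[k, ] <- list(sp$cpd_id, sp$mz, mu_d, sp$sigma, sp$tau,
                       sp$amplitude, apex$rt, area)
  }

  spectra <- with_seed(recipe$seed, {
    mz_jit <- if (np > 0)
      matrix(stats::rnorm(recipe$n_scans * np, 0, recipe$mz_jitter_sd),
             recipe$n_scans, np) else
      matrix(0, recipe$n_scans, 0)
    noise <- if (np > 0)
      matrix(stats::rnorm(recipe$n_scans * np, 0, recipe$noise_sd),
             recipe$n_scans, np) else
      matrix(0, recipe$n_scans, 0)
    base_mz <- vapply(recipe$peaks, `[[`, numeric(1), "mz")
    lapply(seq_len(recipe$n_scans), function(i) {
      mz <- base_mz + mz_jit[i, ]
      inten <- vapply(seq_len(np), function(k)
        model_eval(shapes[[k]], times[i]), numeric(1))
      inten <- pmax(inten + recipe$baseline + noise[i, ], 0)
      o <- order(mz)
      ms_spectrum(i - 1L, times[i], mz[o], inten[o], 1L, TRUE)
    })
  })
  list(run = raw_run(recipe$sample_id, spectra, "positive"), truth = truth)
}

b64_doubles <- function(x) {
  gsub("[[:space:]]", "",
       jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                     endian = "little")))
}

mzml_spectrum_xml <- function(s) {
  mode_cv <- if (s$centroided)
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  type_cv <- if (s$ms_level == 1L)
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>'
  mz_b <- b64_doubles(s$mz)
  it_b <- b64_doubles(s$intensity)
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
            s$scan_index, s$scan_index + 1L, length(s$mz)),
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
            s$ms_level),
    type_cv, mode_cv,
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%s" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
            format(s$rt, digits = 17, scientific = FALSE)),
    '</scan></scanList>',
    '<binaryDataArrayList count="2">',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(mz_b)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    sprintf('<binary>%s</binary></binaryDataArray>', mz_b),
    sprintf('<binaryDataArray encodedLength="%d">', nchar(it_b)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    sprintf('<binary>%s</binary></binaryDataArray>', it_b),
    '</binaryDataArrayList></spectrum>')
}

#' Write a `RawRun` as minimal standards-conformant mzML
#'
#' MS1 centroid spectra, 64-bit little-endian uncompressed arrays, scan
#' start time in seconds.  Round-trips through [read_mzml()].
#'
#' @param run a [raw_run()] object.
#' @param path output file path (.mzML).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  pol_cv <- switch(run$polarity,
    positive = '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
    negative = '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>',
    "")
  body <- vapply(run$spectra, function(s) {
    x <- mzml_spectrum_xml(s)
    if (nzchar(pol_cv))
      x <- sub('<scanList', paste0(pol_cv, '<scanList'), x, fixed = TRUE)
    x
  }, character(1))
  doc <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="eicpeaks" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="eicpeaks"/></dataProcessing></dataProcessingList>',
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">',
            run$sample_id),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="DP1">',
            length(run$spectra)),
    body,
    '</spectrumList></run></mzML>')
  ok <- tryCatch({ writeLines(doc, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write mzML file '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

default_peak_panel <- function(n_peaks, rt_lo, rt_hi, seed) {
  with_seed(seed, {
    mus <- seq(rt_lo, rt_hi, length.out = n_peaks) +
      stats::runif(n_peaks, -5, 5)
    sigmas <- stats::runif(n_peaks, 3, 6)
    taus <- stats::runif(n_peaks, 0, 1) * sigmas
    amps <- 10^stats::runif(n_peaks, 5, 6)
    mzs <- sort(stats::runif(n_peaks, 100, 600))
    lapply(seq_len(n_peaks), function(k)
      peak_spec(sprintf("CPD_%03d", k), mzs[k], mus[k], sigmas[k],
                taus[k], amps[k]))
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `n_samples` mzML runs sharing one peak panel but with per-sample
#' drift and noise realizations, plus the matching ROI CSV (rt windows
#' mu +/- 4 sigma, m/z +/- 0.01 Da), a calibrant CSV (every other compound,
#' expectedRt = undrifted apex rt) and a per-sample truth table.
#'
#' @param n_samples number of runs to generate (>= 1).
#' @param out_dir output directory (created if absent).
#' @param drift inter-sample drift: `list(kind = "none")`,
#'   `list(kind = "offset", values = <per-sample delta or sd = >)`, or
#'   `list(kind = "linear", a = <vector>, b = <vector>)`.  For `"offset"`
#'   either `values` (recycled) or `sd` (random per-sample offsets) may be
#'   given.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param n_peaks number of planted compounds.
#' @param n_scans scans per run.
#' @param scan_interval scan spacing (s).
#' @param rt_start run start time (s).
#' @param noise_sd intensity noise sd (default 2000, i.e. SNR 50-500 for the
#'   default amplitude range 1e5-1e6).
#' @param baseline constant baseline intensity.
#' @param mz_jitter_sd centroid m/z jitter sd (Da).
#' @param peaks optional explicit list of [peak_spec()] (overrides
#'   `n_peaks`).
#' @return list with `files`, `roi_csv`, `calibrant_csv`, `truth_csv`,
#'   `rois` (the `ROISet`) and `truth` (long data frame, one row per
#'   sample x peak).
#' @export
make_dataset <- function(n_samples, out_dir, drift = list(kind = "none"),
                         seed = 1L, n_peaks = 20L, n_scans = 600L,
                         scan_interval = 1, rt_start = 0, noise_sd = 2000,
                         baseline = 100, mz_jitter_sd = 0.001, peaks = NULL) {
  stopifnot(n_samples >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rt_end <- rt_start + (n_scans - 1L) * scan_interval
  if (is.null(peaks))
    peaks <- default_peak_panel(n_peaks, rt_start + 0.1 * (rt_end - rt_start),
                                rt_start + 0.9 * (rt_end - rt_start), seed)
  n_peaks <- length(peaks)

  sample_drift <- function(i) {
    switch(drift$kind,
      none = list(kind = "none"),
      offset = {
        delta <- if (!is.null(drift$values))
          rep_len(drift$values, n_samples)[i]
        else with_seed(seed + 7919L + i, stats::rnorm(1, 0, drift$sd))
        list(kind = "offset", delta = delta)
      },
      linear = list(kind = "linear", a = rep_len(drift$a, n_samples)[i],
                    b = rep_len(drift$b, n_samples)[i]),
      stop("unknown drift kind '", drift$kind, "'", call. = FALSE))
  }

  files <- character(n_samples)
  truth_all <- NULL
  for (i in seq_len(n_samples)) {
    sid <- sprintf("sample_%02d", i)
    rec <- run_recipe(peaks, n_scans = n_scans, rt_start = rt_start,
                      scan_interval = scan_interval, noise_sd = noise_sd,
                      baseline = baseline, mz_jitter_sd = mz_jitter_sd,
                      rt_drift = sample_drift(i), seed = seed + i,
                      sample_id = sid)
    sim <- simulate_run(rec)
    files[i] <- file.path(out_dir, paste0(sid, ".mzML"))
    write_mzml(sim$run, files[i])
    tr <- sim$truth
    tr$sample_id <- sid
    truth_all <- rbind(truth_all, tr)
  }

  undrifted <- data.frame(
    cpd_id = vapply(peaks, `[[`, character(1), "cpd_id"),
    mz = vapply(peaks, `[[`, numeric(1), "mz"),
    mu = vapply(peaks, `[[`, numeric(1), "mu"),
    sigma = vapply(peaks, `[[`, numeric(1), "sigma"),
    stringsAsFactors = FALSE)
  apex0 <- vapply(peaks, function(sp) shape_apex(peak_shape(sp))$rt,
                  numeric(1))
  rois <- as_roiset(data.frame(
    cpdID = undrifted$cpd_id, cpdName = undrifted$cpd_id,
    rtMin = undrifted$mu - 4 * undrifted$sigma, rt = apex0,
    rtMax = undrifted$mu + 4 * undrifted$sigma,
    mzMin = undrifted$mz - 0.01, mz = undrifted$mz,
    mzMax = undrifted$mz + 0.01, stringsAsFactors = FALSE))
  roi_csv <- file.path(out_dir, "roi.csv")
  write_roi_csv(rois, roi_csv)

  cal_idx <- seq(1L, n_peaks, by = 2L)
  calibrant_csv <- file.path(out_dir, "calibrants.csv")
  utils::write.csv(data.frame(cpdID = undrifted$cpd_id[cal_idx],
                              expectedRt = apex0[cal_idx]),
                   calibrant_csv, row.names = FALSE)

  truth_csv <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth_all, truth_csv, row.names = FALSE)

  list(files = files, roi_csv = roi_csv, calibrant_csv = calibrant_csv,
       truth_csv = truth_csv, rois = rois, truth = truth_all)
}
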