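# Dataset-level annotation: batch determinism, summaries, refinement, export.
#
# Sizes are scaled down (few samples, few compounds, short runs) to keep the
# default suite fast; the stated-world sizes live in test-acceptance.R.

local_small_dataset <- function(env = parent.frame(), n_samples = 3,
                                n_peaks = 4, noise_sd = 500,
                                drift = list(kind = "none"), seed = 10) {
  dir <- withr::local_tempdir(.local_envir = env)
  make_dataset(n_samples, dir, drift = drift, seed = seed,
               n_peaks = n_peaks, n_scans = 200, noise_sd = noise_sd)
}

test_that("run_annotation is invariant to worker count and flags bad files", {
  ds <- local_small_dataset()
  cfg1 <- fit_config(workers = 1L)
  cfg4 <- fit_config(workers = 4L)
  s1 <- run_annotation(ds$files, ds$rois, cfg1)
  s4 <- run_annotation(ds$files, ds$rois, cfg4)
  expect_identical(s1$measurements, s4$measurements)
  expect_identical(s1$sample_ids, s4$sample_ids)

  corrupt <- withr::local_tempfile(fileext = ".mzML")
  writeLines("<mzML this is broken", corrupt)
  s <- run_annotation(c(ds$files, corrupt), ds$rois, cfg1)
  expect_equal(length(s$sample_ids), 4L)
  expect_true(!is.na(s$errors[[4]]))
  bad_row <- s$measurements[[4]]
  expect_true(all(!vapply(bad_row, `[[`, logical(1), "found")))
  # valid rows unaffected
  expect_identical(s$measurements[1:3], s1$measurements)
  # all files failing aborts with a summary
  expect_error(run_annotation(corrupt, ds$rois, cfg1), "all input files")
})

test_that("planted peaks are found across the grid", {
  ds <- local_small_dataset(n_samples = 3, n_peaks = 5)
  s <- run_annotation(ds$files, ds$rois, fit_config())
  found <- annotation_matrix(s, "found")
  expect_gte(mean(found), 0.95)
  # areas agree with the generator ledger
  area <- annotation_matrix(s, "area")
  for (i in seq_len(nrow(area))) {
    tr <- ds$truth[ds$truth$sample_id == rownames(area)[i], ]
    rel <- abs(area[i, tr$cpd_id] - tr$true_area) / tr$true_area
    expect_lt(median(rel), 0.08)
  }
})

test_that("summarize_annotation equals brute-force recomputation", {
  ds <- local_small_dataset()
  s <- run_annotation(ds$files, ds$rois, fit_config())
  sm <- summarize_annotation(s)
  found <- annotation_matrix(s, "found") == 1
  area <- annotation_matrix(s, "area")
  apex <- annotation_matrix(s, "apex_rt")
  for (j in seq_len(nrow(ds$rois))) {
    id <- ds$rois$cpdID[j]
    k <- which(sm$cpd_id == id)
    expect_equal(sm$found_fraction[k], mean(found[, j]))
    fa <- area[found[, j], j]
    if (length(fa) > 1)
      expect_equal(sm$area_rsd[k], sd(fa) / mean(fa) * 100)
    dev <- apex[found[, j], j] - ds$rois$rt[j]
    expect_equal(sm$rt_dev_median[k], median(dev))
    expect_equal(sm$rt_dev_iqr[k], IQR(dev))
  }
})

test_that("identical areas give zero RSD and partial detection counts", {
  rois <- as_roiset(data.frame(cpdID = "x", cpdName = "x", rtMin = 0,
                               rt = 5, rtMax = 10, mzMin = 1, mz = 1.5,
                               mzMax = 2))
  mk <- function(found, area)
    eicpeaks:::new_measurement("x", "s", found = found,
                               area = if (found) area else NA_real_,
                               apex_rt = if (found) 5 else NA_real_)
  state <- structure(list(
    sample_ids = paste0("s", 1:10), rois = rois, u_rois = NULL, firs = NULL,
    use_uroi = FALSE, use_fir = FALSE,
    measurements = lapply(1:10, function(i) list(mk(i <= 8, 123))),
    errors = setNames(rep(NA_character_, 10), paste0("s", 1:10)),
    config = fit_config()), class = "AnnotationState")
  sm <- summarize_annotation(state)
  expect_equal(sm$found_fraction, 0.8)
  expect_equal(sm$area_rsd, 0)
})

test_that("propose_refinement: consensus of constants and min_found flag", {
  ds <- local_small_dataset(n_samples = 4, n_peaks = 3, noise_sd = 0)
  s <- run_annotation(ds$files, ds$rois, fit_config())
  ref <- propose_refinement(s, fit_config())
  expect_true(all(ref$u_rois$refined))
  # noiseless identical samples: uROI expected rt equals the common apex
  apex <- annotation_matrix(s, "apex_rt")
  for (j in seq_len(ncol(apex)))
    expect_equal(ref$u_rois$rt[j], median(apex[, j]), tolerance = 1e-9)
  # uROI m/z window never widens beyond the original
  expect_true(all(ref$u_rois$mzMin >= ds$rois$mzMin - 1e-12))
  expect_true(all(ref$u_rois$mzMax <= ds$rois$mzMax + 1e-12))
  # FIR is inside the uROI rt window
  expect_true(all(ref$firs$rtMin >= ref$u_rois$rtMin))
  expect_true(all(ref$firs$rtMax <= ref$u_rois$rtMax))

  # compounds found in fewer than min_found samples keep the original ROI
  cfg_high <- fit_config(min_found = 10L)
  ref2 <- propose_refinement(s, cfg_high)
  expect_true(all(!ref2$u_rois$refined))
  expect_equal(ref2$u_rois$rtMin, ds$rois$rtMin)
  expect_equal(ref2$u_rois$rtMax, ds$rois$rtMax)
})

test_that("refinement is idempotent on a noiseless drift-free dataset", {
  ds <- local_small_dataset(n_samples = 3, n_peaks = 3, noise_sd = 0)
  s1 <- run_annotation(ds$files, ds$rois, fit_config())
  r1 <- propose_refinement(s1, fit_config())
  s2 <- run_annotation(ds$files, ds$rois, fit_config(),
                       u_rois = r1$u_rois, use_uroi = TRUE)
  r2 <- propose_refinement(s2, fit_config())
  # consensus statistics are reproduced; windows agree within pad arithmetic
  expect_equal(r2$u_rois$rt, r1$u_rois$rt, tolerance = 0.01)
  fw <- annotation_matrix(s1, "fwhm")
  pads <- apply(fw, 2, median, na.rm = TRUE)
  expect_true(all(abs(r2$u_rois$rtMin - r1$u_rois$rtMin) <= pads + 1e-6))
  expect_true(all(abs(r2$u_rois$rtMax - r1$u_rois$rtMax) <= pads + 1e-6))
})

test_that("export_tables writes reloadable matrices with empty (not 0) gaps", {
  ds <- local_small_dataset(n_samples = 2, n_peaks = 2)
  s <- run_annotation(ds$files, ds$rois, fit_config())
  # force one not-found cell
  s$measurements[[1]][[1]] <- eicpeaks:::new_measurement(
    ds$rois$cpdID[1], s$sample_ids[1])
  dir <- withr::local_tempdir()
  paths <- export_tables(s, dir)
  expect_true(all(file.exists(paths)))
  area <- read.csv(paths[["area"]], check.names = FALSE)
  expect_equal(dim(area), c(2L, 3L))       # sample_id + 2 compounds
  expect_identical(names(area)[-1], ds$rois$cpdID)
  expect_true(is.na(area[1, 2]))           # empty cell, not zero
  in_mem <- annotation_matrix(s, "area")
  expect_equal(as.numeric(area[2, -1]), unname(in_mem[2, ]),
               tolerance = 1e-9)
})
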