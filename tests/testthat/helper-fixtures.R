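# Shared fixtures and independent oracles.

# Bare EIC from vectors (bypasses extraction).
make_eic <- function(t, y, sample_id = "s1", cpd_id = "c1",
                     mz_weighted = rep(NA_real_, length(t))) {
  structure(list(sample_id = sample_id, cpd_id = cpd_id, rt = t,
                 intensity = y, mz_weighted = mz_weighted,
                 n_scans = length(t), empty = length(t) == 0L),
            class = "EIC")
}

make_roi <- function(cpdID = "c1", rtMin, rtMax, mzMin = 0, mzMax = 1,
                     rt = NA_real_, mz = NA_real_, cpdName = cpdID) {
  list(cpdID = cpdID, cpdName = cpdName, rtMin = rtMin, rt = rt,
       rtMax = rtMax, mzMin = mzMin, mz = mz, mzMax = mzMax)
}

# Independent EMG oracle: direct quadrature of the defining convolution of a
# Gaussian with an exponential decay (never touches the package's erfcx
# closed form).  Integrates over the Gaussian variable s (localized near mu)
# so the quadrature never misses the mass.
emg_conv_oracle <- function(t, A, mu, sigma, tau) {
  vapply(t, function(tt) {
    hi <- min(tt, mu + 15 * sigma)
    lo <- mu - 15 * sigma
    if (hi <= lo) return(0)
    stats::integrate(function(s)
      A * exp(-(s - mu)^2 / (2 * sigma^2)) * exp(-(tt - s) / tau) / tau,
      lo, hi, rel.tol = 1e-12, subdivisions = 2000L)$value
  }, numeric(1))
}

# Brute-force crossing finder on an oversampled curve + bisection refinement,
# independent of peak_metrics' bracketing.
brute_crossing <- function(f, lo, hi, target, n = 20001L) {
  g <- seq(lo, hi, length.out = n)
  v <- f(g)
  s <- sign(v - target)
  i <- which(s[-1] != s[-n])[1]
  stats::uniroot(function(x) f(x) - target, lower = g[i], upper = g[i + 1L],
                 tol = 1e-12)$root
}

mk_obs_acc <- function(observed, expected) {
  data.frame(cpd_id = paste0("c", seq_along(observed)),
             observed_rt = observed, expected_rt = expected,
             stringsAsFactors = FALSE)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / max(abs(expected),
                                         .Machine$double.eps), rel_tol)
}
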