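---
title: "Targeted peak integration: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted peak integration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Untargeted LC–MS pre-processing extracts as many peaks as possible and then
groups them across samples; the cost is unreliable features and heavy
filtering. When the assay is well characterized — the compounds of interest,
their expected retention times and ion m/z values are known in advance — a
targeted formulation is more direct: search each annotated compound inside a
pre-specified retention-time × m/z **region of interest (ROI)**, integrate
its signal, and report a samples × compounds matrix of areas with quality
metrics. `eicpeaks` implements that workflow: extraction, line-shape
fitting, fallback integration, dataset-level consensus refinement, and
calibrant-based retention-time re-calibration, together with a synthetic-run
generator that makes every stage testable without external data.

# Extraction

A raw run is an rt-ordered list of MS1 spectra read from mzML
(`read_mzml()`: 32/64-bit little-endian arrays, zlib or no compression,
rt in seconds or minutes, gzipped files). For each ROI, `extract_eic()`
builds the extracted ion chromatogram (EIC): one point per MS1 scan whose rt
lies in the closed interval `[rtMin, rtMax]`, with intensity equal to the
**sum** of all ion intensities inside the closed `[mzMin, mzMax]` window.
Summation (rather than the per-scan maximum) is the standard EIC definition
and preserves area additivity; it also absorbs profile-mode points without a
centroiding step. Scans with no matching ions contribute zero, so the EIC
grid is always the scan grid and is never resampled — fitting operates on
native scan times.

# Line-shape models

Chromatographic peaks front and tail; a plain Gaussian cannot represent
that. Two asymmetric shapes are fitted (with the Gaussian as a degenerate
case):

* **Skew-normal-scaled Gaussian**
  $f(t) = b + A\,e^{-(t-\mu)^2/2\sigma^2}\,
  \bigl(1 + \mathrm{erf}\!\bigl(\tfrac{\alpha (t-\mu)}{\sigma\sqrt 2}\bigr)\bigr)$,
  with dimensionless skew $\alpha$ ($\alpha = 0$ recovers the Gaussian
  exactly; negative $\alpha$ fronts, positive tails).

* **Exponentially modified Gaussian (EMG)** — the convolution of a Gaussian
  with an exponential decay of time constant $\tau$:
  $f(t) = b + \tfrac{A\sigma}{\tau}\sqrt{\tfrac{\pi}{2}}\,
  e^{\sigma^2/2\tau^2 - (t-\mu)/\tau}\,
  \mathrm{erfc}\!\bigl(\tfrac{\sigma/\tau - (t-\mu)/\sigma}{\sqrt 2}\bigr)$.
  The naive form overflows for $\tau \ll \sigma$; evaluation goes through
  the scaled complementary error function, computing
  $\log\mathrm{erfcx}(z) = z^2 + \log 2 + \log\Phi(-z\sqrt2)$ with the
  log-scale normal CDF, so the model is finite for any finite $t$ and any
  $\tau > 0$.

A numerical note on the Gaussian limit: as $\tau \to 0^+$ the EMG tends to
the Gaussian, but at first order the convolution shifts the mean by $\tau$,
so the *pointwise relative* deviation at $|t-\mu| = 3\sigma$ is
$\approx 3\tau/\sigma$ (3% at $\tau = \sigma/100$) for any correct EMG
implementation. The limit checks in the test suite therefore measure the
deviation relative to the apex height (0.6% at $\tau = \sigma/100$) and
verify the closed form against direct quadrature of the defining
convolution to $10^{-8}$.

# Fitting, acceptance and fallback

`guess_initial()` seeds the optimizer from the data: location at the
intensity argmax, baseline as the mean of the lowest intensity decile,
$\sigma$ from the interpolated width at half apex divided by 2.355 (clipped
to [scan interval, rt span]), and small positive starting values for
$\tau$/$\alpha$. `fit_curve()` runs bounded nonlinear least squares
(L-BFGS-B on intensities scaled to unit maximum), with $\mu$ confined to
the EIC rt range, $\sigma \in$ [scan interval/2, rt span] and
$A \in (0, 2\max y]$. An abnormal line-search exit is retried from the
returned point (at most twice); a persistent failure or a physical
parameter pinned at its bound is recorded as `converged = FALSE`, never
raised.

`measure_peak()` accepts a fit when it converged **and** the residual RMSE
divided by apex height is at most `max_residual` (default 0.35) **and** the
apex lies inside the ROI rt window **and** the FWHM does not exceed the
window span. The default model chain is EMG, then skew-Gaussian. On
acceptance the area is the model integral (adaptive quadrature) over the
5%-height extent — not $(-\infty,\infty)$ — so model and fallback areas are
comparable on the same support. Width is the FWHM; asymmetry is the USP
tailing factor $(a+b)/(2a)$ at 5% of apex height; both are found by
bisection on the fitted curve.

When no fit is acceptable (shoulders, split peaks, gross shape deviation),
`fallback_area()` integrates the raw points by the trapezoidal rule over
the ROI rt window (or the tighter FIR window, below), after subtracting the
straight baseline joining the window-edge intensities and clipping at zero.

A peak is **found** when its apex height reaches `min_height_k` (default 3)
times the baseline noise sd, estimated robustly as
$\mathrm{MAD}(\Delta y)/\sqrt 2$ — insensitive to the peak occupying part
of the trace. The acceptance threshold, detection multiplier and 5%-height
extent convention are not prescribed by any reference; they are exposed in
`fit_config()` and chosen for robustness on the synthetic benchmarks.

# Dataset aggregation and consensus refinement

`run_annotation()` maps the extraction + measurement over all files. Per-
file work is free of random numbers and independent, so results are
bit-identical for any worker count; a corrupt file yields an all-not-found
row with an error note instead of aborting the batch.

`propose_refinement()` turns a completed first pass into tighter windows
for a second one. For each compound found in at least `min_found` (default
3) samples:

* **uROI** rt window = [min observed 5%-extent start − pad, max observed
  5%-extent end + pad], pad defaulting to one median FWHM; expected rt =
  median apex rt. The m/z window is the observed m/z range padded by
  `mz_pad` (0.005 Da) but **never wider than the original ROI** — widening
  toward a neighbouring isobar is exactly the failure mode consensus should
  prevent.
* **FIR** (fallback integration region) rt window = [median extent start,
  median extent end]; m/z window = the uROI one.

Compounds below `min_found` keep their original ROI and are flagged.
Refinements are returned (and exported) as data; they are applied only when
`use_uroi`/`use_fir` are set, mirroring a review-then-apply workflow. The
median was chosen as the consensus statistic over a trimmed mean: with the
small per-compound sample counts typical of a first pass it has a simpler
breakdown story, and on a drift-free dataset it makes refinement idempotent
(verified in the suite). Measurements obtained via fallback carry a
data-derived 5%-height extent so they still contribute to consensus.

# Retention-time re-calibration

Retention times drift between batches. Given calibrants (spiked standards
or reliable endogenous compounds) with expected rts, `fit_rt_ransac()` fits
expected = f(observed) — calibrants are measured in the new run's frame, so
this is the unambiguous direction — by classic RANSAC: 500 seeded
iterations, each fitting a minimal subset exactly (offset 1 point, linear
2, polynomial d+1), counting inliers within 5 s, keeping the largest
consensus (ties: lower inlier RMSE, then earlier iteration), and refitting
by least squares on the consensus inliers. With zero outliers this is
provably plain least squares on all points (tested to 1e-9). The
calibration fails loudly when fewer than `min_inlier_fraction` (0.5) of
calibrants agree.

`apply_rt_model()` corrects the ROI **windows**, not the data: each rt
boundary is pushed through $f^{-1}$ (closed form for offset/linear; for
polynomials, monotone numerical inversion on the run's rt range, refusing
non-monotone maps — a decreasing or folded rt map is physically
meaningless). Spectra are never warped or resampled.

# The synthetic world

`simulate_run()` builds runs in which everything is known: each planted
compound contributes one centroid per scan at its m/z (plus Gaussian jitter,
sd 0.001 Da) whose intensity follows its Gaussian/EMG shape at the scan
time, on a constant baseline with additive Gaussian noise clipped at zero.
The ledger records each peak's drifted apex rt (located numerically) and
true area (quadrature at generation time, equal to $A\sigma\sqrt{2\pi}$ for
both shapes since convolution preserves area). `make_dataset()` defaults
describe a plausible small profiling panel: 20 compounds across m/z
100–600, apexes over the middle 80% of a 600 s run sampled at 1 Hz,
$\sigma \in [3, 6]$ s, $\tau \in [0, \sigma]$ (moderate tailing),
amplitudes $10^5$–$10^6$ against noise sd 2000 (SNR 50–500), ROI windows
$\mu \pm 4\sigma$ and m/z ± 0.01 Da. Inter-sample drift can be none, a
per-sample offset (fixed values or drawn with a given sd) or linear in rt.

What the generator does **not** emulate: isotope patterns and adducts,
chimeric/overlapping isobars, detector saturation, heteroscedastic
shot noise, spray instability, and profile-mode m/z peak shapes (a
centroid-per-compound world). A green synthetic benchmark therefore
establishes correctness of the algorithms under the stated model — not
performance on matrix effects the model excludes.

# Numerical choices and degenerate inputs

* Quadrature: `stats::integrate`, rel. tol 1e-9 (1e-10 for ledger areas).
* Crossings (FWHM, 5% extent): outward bracketing from the apex in
  $\sigma$-sized steps, then `uniroot` at tol 1e-10.
* Empty rt window → flagged empty EIC, not an error; all-zero EIC →
  not-found measurement; fewer than 5 points → fallback path only.
* Noise sd 0 (noiseless data) makes the detection threshold 0: any positive
  apex is found — intentional, so noiseless fixtures behave as expected.
* CSV numerics are written at 17 significant digits; round-trips are
  lossless to 1e-9 relative (tested).
* All stochastic components (generator, RANSAC) draw under local seeds that
  save and restore the caller's RNG state.

# Known limitations

One peak per ROI (targeted, not untargeted, picking: no deconvolution of
co-eluting isomers inside a window); constant or edge-linear baseline only;
no ion mobility, no MS2, no vendor formats; the mzML writer emits the
minimal subset the reader consumes (sufficient for standards-conformant
MS1 centroid data, not a general-purpose exporter).
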