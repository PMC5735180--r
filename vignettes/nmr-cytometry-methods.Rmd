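---
title: "Methods: quantitative 19F NMR cytometry, from FID to biodistribution"
author: "nmrcytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative 19F NMR cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcytometry)
```

## The measurement model

19F NMR "cytometry" counts perfluorocarbon (PFC)-labeled cells inside intact
tissue samples.  Cells are loaded in culture with a PFC nanoemulsion whose
dominant resonance sits at -91.58 ppm; fluorine is essentially absent from
soft tissue, so the integral of that peak is proportional to the number of
19F nuclei — and hence, via the mean per-cell loading measured at infusion,
to an *apparent* number of labeled cells.  Absolute spectrometer response is
unknown (receiver gain, coil loading), so every tube also contains a sealed
trifluoroacetate (TFA) capillary of known fluorine content resonating at
-76 ppm.  The chain is:

1. **Per-cell loading** from labeled cell pellets:
   $L = \dfrac{(I_{PFC}/I_{TFA})\,N_{TFA}}{n_{cells}}$, where $N_{TFA}$ is
   the fluorine atom count of the reference aliquot computed from its recipe
   (mass fraction, volume, molar mass, 3 fluorines per molecule).
2. **Tissue 19F content**: $N = (I_{PFC}/I_{TFA})\,N_{TFA}$ per organ.
3. **Apparent cells** $= N / L$; **percent injected dose**
   $= 100\,N / (n_{inj} L)$; the tail's content estimates the mis-injected
   fraction, giving a corrected intravenous dose
   $n_{inj} - N_{tail}/L$.
4. **Limit of detection**: SNR of calibration standards is regressed through
   the origin on atom count; the LOD is the content where the extrapolated
   SNR reaches a threshold (2 by default), divided by $L$ for a cell-number
   LOD.

Two physical assumptions carry the quantification:

* **T1 matching.** Under repeated pulsing at recycle delay $TR$, each
  species' signal is attenuated by the steady-state factor
  $f = (1-E)\sin\theta/(1-E\cos\theta)$, $E = e^{-TR/T_1}$.  The reference
  capillary is doped with MnCl2 so TFA's $T_1$ matches the tracer's
  (~0.47 s at 9.4 T); the factors then cancel in $I_{PFC}/I_{TFA}$ at any
  $TR$.  `steady_state_factor()` implements the factor, the simulator applies
  it per line, and the test suite verifies that matched $T_1$ makes
  quantification $TR$-independent while a 2x mismatch reproduces the
  analytic factor ratio.
* **Whole-sample detection.** Samples are assumed to fit the coil's receptive
  field, so integrals represent all 19F in the tube.  Pooled low-signal
  organs are treated as a single sample whose uncertainty is the
  noise-propagated integral SE rather than a between-animal SE.

## Spectral processing

`fid_to_spectrum()` applies optional exponential apodization (`lb` in Hz of
added Lorentzian width), halves the first FID point (so the discrete
transform samples the continuous one-sided Fourier transform without a DC
pedestal), zero-fills (factor 2 by default), Fourier transforms and scales by
the dwell time.  The ppm axis is stored descending.

**Automatic phasing.** The protocol applies phase correction without fixing
an algorithm, so the package's choice favours determinism and noise robustness:
peaks are located on the (phase-invariant) magnitude spectrum — inside
declared windows when the caller provides them, otherwise by iterative
peak-picking with masking — and the phase that renders each peak absorptive
is read off as minus the argument of its locally-detrended, triangularly
weighted complex sum around the sub-grid apex.  A weighted linear fit of
per-peak phase against position gives $(\phi_0, \phi_1)$; wrap ambiguities
between peaks are scored with a negative-absorption penalty.  Reading phases
at the peaks, rather than optimising the penalty itself, matters: with one
intense reference line, a fraction of a degree of phase error leaks the
line's dispersive tail (decaying only as $1/\Delta$) across the spectrum.
The first-order phase is bounded (+/-200 degrees across the window) because
larger ramps are degenerate for sparse spectra.

**Baseline.** A global polynomial (order 0-3, default 1) is fitted outside
the declared peak windows and subtracted.  In addition, `integrate_peak()`
can subtract a straight line fitted to each window's flanking margins — the
bias/slope correction of standard quantitative-NMR integration.  This local
correction is what makes small tracer peaks quantifiable next to a reference
up to ~800x stronger: the reference's smooth absorptive and residual
dispersive tails are locally linear over the +/-1.5 ppm window and cancel.
The flank subtraction inflates the integral's noise SE by
$\sqrt{1 + n/n_{flank}}$, which the reported SE includes.

**ppm calibration.** The axis is shifted so the detected reference peak lands
exactly at -76 ppm; a shift larger than 10 ppm, or a reference window with no
detectable peak, is treated as mis-identification and raises an error.

**Integration and errors.**  Integrals are trapezoidal with the window edges
linearly interpolated (so the captured fraction does not jump with grid
alignment).  The noise SE follows the baseline-noise prescription: RMS of a
signal-free region times the axis step times the square root of the number of
points in the window — with two corrections derived here: zero-filling makes
adjacent points correlated (effective count $nz/2$ for zero-fill factor
$z \ge 2$), and the local flank correction adds its own propagated noise.  A
property test checks the resulting SE against the empirical SD of
signal-free-window integrals over hundreds of noise draws (within 10%).

**SNR conventions.**  `compute_snr()` is peak maximum over noise RMS with no
vendor factor of 2 (some vendor software divides by twice the noise; the LOD
threshold is a configuration constant, so either convention's "SNR = 2" can
be reproduced).  The max statistic is the right convention for strong
calibration standards but is positively biased on weak samples (the maximum
of hundreds of noise points is ~3 sigma), so the per-sample *below-LOD flag*
instead uses the baseline-corrected peak height read at the known tracer
shift (mean of the 5 central points), which is unbiased in the absence of
signal.  Samples below the flag threshold are reported and annotated, never
zeroed, and are excluded from group tests.

## The synthetic-data generator

The generator stands in for the study's measurements and defines the
conditions under which the pipeline is validated.

**FIDs.**  Each resonance contributes
$A\,f\,e^{(i2\pi\Delta f - 1/T_2^*)t}$ with amplitude proportional to its
19F atom count times an arbitrary receiver gain (so atoms are only
recoverable through the reference, as on a real spectrometer), attenuated by
its steady-state factor.  Averaging multiplies signal by the number of scans
and complex Gaussian noise by its square root, so SNR scales as
$\sqrt{n_{avg}}$ (verified: log-log slope 0.5 +/- 0.05).  Defaults mirror the
acquisition protocol: 376.5 MHz 19F, 100 ppm spectral width, 32,000 complex
points, 17 us pulse, recycle delays of 1.5 s (tissues), 5 s (cell pellets)
and 10 s (LOD standards), 32-1024 averages.  $T_2^*$ defaults (50 ms tracer,
80 ms reference; linewidths ~6.4 and ~4 Hz) are plausible for well-shimmed
liquid-state samples; tests that shorten the FID scale $T_2^*$ down
proportionally so the acquisition always spans ~17 tracer $T_2^*$ and
truncation artefacts do not enter.

**Noise calibration.**  Probe sensitivity is specified as expected SNR per
1e15 atoms at 128 averages, back-computed from the reported detection
limits: 2/1.4 for the 5 mm probe (LOD 7e3 cells at 2e11 atoms/cell and
SNR 2) and 2/8 for the 10 mm probe (4e4 cells).  The generator converts
sensitivity to a time-domain noise sigma through a cached noiseless
calibration of processed peak height per atom.

**Study bookkeeping.**  Label kinetics are deterministic exponential
bookkeeping, not agent-based: each treated mouse's dose (2e7 cells at
2e11 atoms/cell) is split at transfer into a tail deposit (mis-injection
fraction, default 5% — tail signal is observed in such studies without the
fraction being quantified; 5% is a typical tail-vein miss), per-organ homing
fractions, and an immediately-cleared remainder.  Homed cells die at a
constant rate (default 0.05/day, a ~2-week T cell half-life) and their label
transfers instantaneously to the liver (Kupffer uptake); division halves the
per-cell label every `division_interval_h` (36 h) while conserving each
organ's total, which is exactly why the *apparent* cell number undercounts
true cells at late timepoints.  Totals over organs + tail + cleared equal
the injected dose to machine precision at every timepoint — a tested
invariant.  CAR homing fractions are back-computed from the reported day-2
biodistribution (tumor ~85,000 apparent cells, spleen ~5e5, liver ~15% of
the injected dose); untransduced fractions halve the spleen and cut the
tumor tenfold, matching the reported contrasts.  Between-animal lognormal
jitter on the fractions (CV 0.25) reproduces the dispersion implied by the
reported SEMs (spleen 5 +/- 0.7e5 over n = 5 gives total CV ~0.31, part of
which is measurement noise).

Two modelling choices deserve flags.  The dead-cell label of *unhomed*
(cleared) cells is not routed to the liver, because the release/re-uptake
kinetics after cell death are not characterised; the cost is that late
liver accumulation is underpredicted (the model reaches ~20% of the injected
dose by day 14 where the study reports 33%), while day-2 liver uptake and
conservation are exact.  And homing fractions are constant per group (time
dependence arises only through death/division), since a freely time-varying
homing table cannot conserve label without an explicit trafficking model.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: static-field inhomogeneity beyond a single
Lorentzian $T_2^*$ (no shim-dependent lineshapes), minor PFC end-group
resonances (the tracer is one line, as only the main peak is quantified),
chemical-shift temperature drifts, probe ringdown/baseline roll,
radiation damping, and any biological kinetics beyond exponential
death/division.  Recovery and coverage results certify the analysis chain
under its own noise model, not spectrometer-specific artefacts.

## Statistics

Group comparisons follow the study's choices: Welch's unequal-variance
t-tests for pairs, one-way ANOVA with Bonferroni-corrected pairwise Welch
tests (family-wise 5%) across three groups, Pearson correlation for the
histology cross-validation, and cytotoxicity expressed as
$100(1 - \bar{x}_{treated}/\bar{x}_{untreated})$ with delta-method SEs.  All
wrap base R (`t.test`, `aov`, `cor.test`) and are verified against
brute-force formula implementations to 1e-10 relative in the test suite.
Pooled samples enter reports with their noise-based SE; below-LOD entries
are excluded from testing and the affected comparisons annotated "not
testable".  p-values are reported to 4 significant figures and never as 0.
Degenerate inputs have documented conventions: identical constant groups
give $p = 1$; all-constant ANOVA input raises an error rather than
fabricating an F statistic.

In the bundled bioluminescence emulation each mouse carries bilateral
tumors and each tumor is an observation, consistent with the reported
degrees of freedom exceeding the number of mice; per-mouse averaging is a
configuration choice away for sensitivity analysis.

## Numerical and interface choices

* Integration windows default to +/-1.5 ppm around each peak — more than 30
  linewidths at the simulated $T_2^*$ — and the noise region to
  [-120, -110] ppm, far from both peaks.  Windows are always specified in
  ppm, never points.
* The LOD fit is through the origin (SNR must vanish with content); a
  free-intercept variant is available for sensitivity analysis.  Whether the
  original extrapolation was linear or log-log is not documented; the linear
  through-origin form is the default and exact on noiseless calibrations.
* Error propagation is first-order (delta method) throughout, matching the
  noise-based SE prescription and testable by Monte Carlo: empirical 95% CI
  coverage of apparent-cell estimates is required to land in [90%, 99%] at
  SNR well above detection.
* Reproducibility: one top-level seed; per-sample seeds derive from it by a
  fixed counter scheme (`derive_seed()`), so any subset of a dataset can be
  regenerated; every processing step is appended to a record that
  `replay_processing()` re-executes bit-identically; `run_pipeline()` hashes
  all artifacts into a manifest and identical configurations reproduce
  identical files.
* Pooling additivity is exact only up to each sample's own far-tail
  crosstalk between the tracer and reference windows (~1e-4 relative with
  the local flank correction), which is the measurement's physical floor,
  not an implementation tolerance.

## Problem sizes

Unit tests run on compact acquisitions (1024-8192 complex points with
$T_2^*$ scaled to keep the truncation regime of the full protocol);
acceptance-level checks run the full 32,000-point protocol: 50-sample
recovery grids, 20-seed phase-recovery and power checks, 100-seed LOD
Monte Carlo, and a 20-seed end-to-end power study at the study's group size
(5 mice per group and timepoint, 6 organs).  The bundled demo study
simulates 2 groups x 15 mice x 6 organs (156 NMR samples including pooled
tubes) in roughly ten seconds on one core.

## Known limitations

Apparent cell numbers ignore in vivo division by design (an optional
$2^{t/T_{div}}$ correction is provided but off by default); late-time liver
fractions are underpredicted as discussed; the phase estimator assumes at
least one peak clearly above the noise floor and falls back to zero phase
(flagged `low_signal`) otherwise; JCAMP-DX support covers plain AFFN
`(X++(Y..Y))` blocks only; and the Bruker-style reader/writer round-trips
this package's own minimal directory layout rather than full vendor
datasets.
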