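# nmrcytometry

Quantitative ¹⁹F NMR "cytometry": counting perfluorocarbon (PFC)-labeled
cells inside intact tissue samples from one-dimensional ¹⁹F NMR spectra.

## The problem

Adoptive cell therapies (for example CAR T cells) need preclinical readouts
of where transferred cells go and how long they persist. Histology samples
small tissue "bites"; flow cytometry requires dissociation. ¹⁹F NMR of whole
fixed organs offers a rapid alternative: cells are labeled in culture with a
PFC nanoemulsion (dominant resonance at −91.58 ppm), tissue contains
essentially no endogenous fluorine, and every NMR tube carries a sealed
trifluoroacetate (TFA) reference capillary of known fluorine content
(−76 ppm) whose T1 is matched to the tracer's (~0.47 s) with MnCl₂, so the
integral ratio is unbiased at short recycle delays.

The core quantities, per tissue sample:

- **¹⁹F content** `N = (I_PFC / I_TFA) · N_TFA`, with a noise-propagated
  standard error from the baseline RMS over the same integral width;
- **apparent cell number** `N / L`, where `L` is the mean ¹⁹F per cell
  measured at infusion (apparent, because in vivo division dilutes the
  per-cell label while conserving the total);
- **percent injected dose** `100 · N / (n_inj · L)`, and a tail-corrected
  effective intravenous dose `n_inj − N_tail / L`;
- **limit of detection**: SNR of a dilution series regressed through the
  origin on atom count; the LOD is the content where the extrapolated SNR
  reaches 2.

The package implements the full chain — synthetic FID and multi-organ study
generation with known ground truth, spectral processing (FT, automatic
phasing, baseline correction, ppm calibration, windowed integration with
calibrated errors), quantification, and the study statistics (Welch t-tests,
one-way ANOVA with Bonferroni correction, Pearson correlation, cytotoxicity
percentages, biodistribution reports). The methods vignette
(`vignettes/nmr-cytometry-methods.Rmd`) documents the models, defaults and
numerical choices.

## Worked example

Simulate one spleen-like sample — 5 × 10⁵ labeled cells at
2 × 10¹¹ ¹⁹F atoms/cell next to the 0.1% w/v TFA capillary — and quantify it:

```r
library(nmrcytometry)

acq <- acquisition_params(n_averages = 512L, recycle_delay = 1.5)
cap <- reference_capillary()            # 0.1% w/v TFA, 50 ul, T1-matched
reference_atoms(cap)
#> [1] 7.922294e+17

pfc <- pfc_line(5e5 * 2e11)             # tracer line, -91.58 ppm
tfa <- tfa_line(reference_atoms(cap))   # reference line, -76 ppm
sigma <- nmrcytometry:::noise_sigma_for_sensitivity(acq, pfc, 2 / 1.4)
fid <- simulate_fid(acq, list(pfc, tfa), noise_sigma_per_scan = sigma,
                    seed = 42)

cfg <- quant_config(ref_capillary = cap,
                    loading = cell_loading(2e11, 0.5e11, 3L),
                    injected_cells = 2e7)
quantify_sample(fid, cfg)
#>      f19_atoms       f19_se apparent_cells cells_se percent_id percent_id_se
#> 1 9.867024e+16 1.104157e+15       493351.2 123461.3   2.466756    0.02760393
#>        snr below_lod
#> 1 288.4663     FALSE
```

The sample's true content was 10¹⁷ atoms (5 × 10⁵ cells): the pipeline
recovers 9.87 × 10¹⁶ atoms (−1.3%) and 493,351 apparent cells at 2.47% of
the injected dose; the large `cells_se` is dominated by the 25% uncertainty
of the loading itself. A detection-limit calibration for a 5 mm probe:

```r
cal <- simulate_calibration_series(
  acquisition_params(n_averages = 128L, recycle_delay = 10),
  10^seq(15.5, 19, 0.5), sensitivity = 2 / 1.4, seed = 7)
snr <- sapply(cal, function(f)
  compute_snr(fid_to_spectrum(f), peak_window(-76, 1.5),
              peak_window(-115, 5)))
estimate_lod(attr(cal, "atom_counts"), snr, threshold = 2,
             loading = cell_loading(2e11), probe = "5mm")
#> <lod_result> [5mm] SNR threshold 2: 1.392e+15 atoms = 6.96e+03 cells
#>   (slope 1.437e-15 SNR/atom, R2 1.0000)
```

i.e. about 7 × 10³ cells per sample for the 5 mm probe.

## The analysis workflow

`analysis/` holds the numbered drivers of the full study emulation; each is
a thin script over the package and writes its tables under `results/`:

1. `01_simulate_study.R` — two-group study (CAR vs untransduced, 15
   mice/group, days 2/7/14, six organs + tail), ground truth retained and
   ¹⁹F conservation audited to machine precision;
2. `02_quantify_biodistribution.R` — processes all 156 FIDs into the
   biodistribution table (day-2 CAR tumor ≈ 8.1 × 10⁴ apparent cells,
   spleen ≈ 4.6 × 10⁵, liver ≈ 15.5% of the injected dose);
3. `03_limits_of_detection.R` — LOD calibration for the 5 mm and 10 mm
   probes (≈ 7 × 10³ and ≈ 4 × 10⁴ cells);
4. `04_study_report.R` — group contrasts (day-2 tumor and spleen Welch
   p < 10⁻⁴), cytotoxicity percentages (CAR 92.6%, untransduced 50.7% at
   24 h), day-7 radiance ANOVA and the NMR-vs-histology correlation.

`run_pipeline(pipeline_config(seed = 1), "out/")` executes the same stages
as one reproducible unit with an artifact manifest.

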