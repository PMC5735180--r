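# Molar masses (g/mol) of supported reference compounds
.reference_molar_mass <- c("TFA" = 114.02, "sodium-TFA" = 136.01)
.avogadro <- 6.022e23

#' Internal reference capillary / aliquot of known 19F content
#'
#' Describes the trifluoroacetate standard co-measured with every sample: the
#' ex vivo protocol uses a sealed capillary of 0.1% (w/v) TFA doped with
#' 0.325 mM MnCl2 so its 19F T1 matches the tracer's (~0.47 s); the in vitro
#' loading assay uses a 50 ul aliquot of 0.1% sodium trifluoroacetate in D2O.
#' The number of 19F atoms is derived from the recipe:
#' `atoms = mass_fraction/100 * volume_ml * 1000 mg/ml-scale / molar_mass *
#' Avogadro * 3` (three fluorines per molecule).
#'
#' @param compound `"TFA"` (114.02 g/mol) or `"sodium-TFA"` (136.01 g/mol).
#' @param mass_fraction Concentration in % w/v (g per 100 ml).
#' @param volume_ul Volume of the aliquot in microlitres.
#' @param T1 19F T1 of the reference in seconds.  A warning is raised when it
#'   differs from `pfc_T1` by more than 20%, because an unmatched T1 biases the
#'   integral ratio at short recycle delays.
#' @param pfc_T1 Tracer T1 used for the matching check.
#' @return An object of class `reference_capillary` with a `derived_atoms`
#'   field.
#' @export
reference_capillary <- function(compound = c("TFA", "sodium-TFA"),
                                mass_fraction = 0.1, volume_ul = 50,
                                T1 = 0.47, pfc_T1 = 0.47) {
  compound <- match.arg(compound)
  if (!is.finite(mass_fraction) || mass_fraction < 0) {
    stop("`mass_fraction` must be >= 0 (% w/v)", call. = FALSE)
  }
  if (!is.finite(volume_ul) || volume_ul <= 0) {
    stop("`volume_ul` must be positive", call. = FALSE)
  }
  if (abs(T1 - pfc_T1) > 0.2 * pfc_T1) {
    warning(sprintf(
      "reference T1 (%.3g s) differs from tracer T1 (%.3g s) by more than 20%%; quantification will be biased unless recycle delay >> T1",
      T1, pfc_T1), call. = FALSE)
  }
  grams <- mass_fraction / 100 * (volume_ul / 1000)  # % w/v = g/100 ml = mg/ml
  atoms <- grams / .reference_molar_mass[[compound]] * .avogadro * 3
  structure(
    list(compound = compound, mass_fraction = mass_fraction,
         volume_ul = volume_ul, f19_per_molecule = 3L, T1 = T1,
         derived_atoms = atoms),
    class = "reference_capillary"
  )
}

#' Number of 19F atoms in a reference aliquot
#'
#' @param capillary A [reference_capillary()].
#' @return Atom count (numeric scalar).
#' @export
reference_atoms <- function(capillary) {
  stopifnot(inherits(capillary, "reference_capillary"))
  capillary$derived_atoms
}

#' 19F content of a sample from the tracer/reference integral ratio
#'
#' `atoms = (pfc$value / ref$value) * ref_atoms`, with a first-order
#' (delta-method) standard error propagating both integral noise SEs:
#' `se/atoms = sqrt((pfc$noise_se/pfc$value)^2 + (ref$noise_se/ref$value)^2)`.
#'
#' @param pfc [integrate_peak()] result for the tracer peak (-91.58 ppm).
#' @param ref [integrate_peak()] result for the reference peak (-76 ppm); must
#'   exceed three times its own noise SE.
#' @param ref_atoms Number of 19F atoms in the reference.
#' @return A list with `atoms` and `se`.
#' @export
f19_content <- function(pfc, ref, ref_atoms) {
  stopifnot(inherits(pfc, "integral_result"), inherits(ref, "integral_result"))
  if (ref$value <= 3 * ref$noise_se) {
    stop("reference peak unreliable (integral <= 3 x its noise SE)",
         call. = FALSE)
  }
  atoms <- pfc$value / ref$value * ref_atoms
  rel2 <- (ref$noise_se / ref$value)^2
  if (pfc$value != 0) rel2 <- rel2 + (pfc$noise_se / pfc$value)^2
  se <- if (pfc$value != 0) abs(atoms) * sqrt(rel2) else
    pfc$noise_se / ref$value * ref_atoms
  list(atoms = atoms, se = se)
}

#' Per-cell 19F loading
#'
#' Constructs or measures the mean number of 19F atoms carried per labeled
#' cell.  `per_cell_loading()` divides the measured 19F content of replicate
#' cell pellets by their cell counts and aggregates replicates as
#' mean +/- standard error.
#'
#' @param mean_atoms_per_cell Mean loading (atoms/cell, > 0 unless content 0).
#' @param se Standard error of the mean loading.
#' @param n_replicates Number of replicates behind the estimate.
#' @return An object of class `cell_loading`.
#' @export
cell_loading <- function(mean_atoms_per_cell, se = 0, n_replicates = 1L) {
  if (!is.finite(mean_atoms_per_cell) || mean_atoms_per_cell < 0) {
    stop("`mean_atoms_per_cell` must be >= 0", call. = FALSE)
  }
  if (!is.finite(se) || se < 0) stop("`se` must be >= 0", call. = FALSE)
  structure(
    list(mean_atoms_per_cell = mean_atoms_per_cell, se = se,
         n_replicates = as.integer(n_replicates)),
    class = "cell_loading"
  )
}

#' @rdname cell_loading
#' @param content 19F content (atoms) of each replicate sample.
#' @param cell_count Number of cells in each replicate (> 0).
#' @export
per_cell_loading <- function(content, cell_count) {
  if (length(cell_count) == 1) cell_count <- rep(cell_count, length(content))
  if (length(content) != length(cell_count)) {
    stop("`content` and `cell_count` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(cell_count)) || any(cell_count <= 0)) {
    stop("`cell_count` must be positive", call. = FALSE)
  }
  per_cell <- content / cell_count
  n <- length(per_cell)
  se <- if (n > 1) stats::sd(per_cell) / sqrt(n) else 0
  cell_loading(mean(per_cell), se, n)
}

#' Apparent number of labeled cells in a sample
#'
#' Divides the sample's 19F content by the mean per-cell loading measured at
#' infusion.  The estimate deliberately ignores in vivo cell division (division
#' dilutes the label per cell while conserving the total), hence "apparent";
#' `division_corrected = TRUE` additionally multiplies by
#' `2^(hours / division_interval_h)` for sensitivity analyses.
#'
#' @param content 19F content in atoms.
#' @param loading A [cell_loading()] with positive mean.
#' @param content_se Standard error of `content`.
#' @param division_corrected Apply the optional division correction
#'   (off by default).
#' @param hours,division_interval_h Elapsed time and division interval used by
#'   the optional correction.
#' @return A list with `cells` and `se` (content and loading SEs combined in
#'   quadrature on the relative scale).
#' @export
apparent_cell_number <- function(content, loading, content_se = 0,
                                 division_corrected = FALSE, hours = 0,
                                 division_interval_h = 24) {
  stopifnot(inherits(loading, "cell_loading"))
  if (loading$mean_atoms_per_cell <= 0) {
    stop("`loading` mean must be positive", call. = FALSE)
  }
  cells <- content / loading$mean_atoms_per_cell
  if (division_corrected) cells <- cells * 2^(hours / division_interval_h)
  rel2 <- (loading$se / loading$mean_atoms_per_cell)^2
  if (content != 0) rel2 <- rel2 + (content_se / content)^2
  se <- if (content != 0) abs(cells) * sqrt(rel2) else
    content_se / loading$mean_atoms_per_cell
  list(cells = cells, se = se)
}

#' Percent injected dose represented by a sample's 19F content
#'
#' `100 * content / (injected_cells * loading$mean_atoms_per_cell)`.
#'
#' @param content 19F content in atoms.
#' @param injected_cells Number of labeled cells infused (> 0).
#' @param loading A [cell_loading()] with positive mean.
#' @return Percentage of the injected 19F dose.
#' @export
percent_injected_dose <- function(content, injected_cells, loading) {
  stopifnot(inherits(loading, "cell_loading"))
  if (injected_cells <= 0 || loading$mean_atoms_per_cell <= 0) {
    stop("`injected_cells` and loading mean must be positive", call. = FALSE)
  }
  100 * content / (injected_cells * loading$mean_atoms_per_cell)
}

#' Effective intravenous dose after tail mis-injection correction
#'
#' Part of a tail-vein injection can be deposited in the tail's subcutaneous
#' tissue; the tail's measured 19F content identifies that missed fraction, and
#' the actually delivered dose is
#' `injected_cells - tail_content / loading$mean_atoms_per_cell`.
#'
#' @param injected_cells Nominal number of cells infused.
#' @param loading A [cell_loading()].
#' @param tail_content Measured 19F content of the tail (atoms); must not
#'   exceed the total injected 19F.
#' @return Effective number of cells delivered intravenously.
#' @export
effective_iv_dose <- function(injected_cells, loading, tail_content) {
  stopifnot(inherits(loading, "cell_loading"))
  if (tail_content > injected_cells * loading$mean_atoms_per_cell) {
    stop("tail 19F content exceeds the injected dose", call. = FALSE)
  }
  injected_cells - tail_content / loading$mean_atoms_per_cell
}

#' Limit of detection from an SNR calibration series
#'
#' Fits the calibration relation SNR = slope * atoms (through the origin by
#' default, since SNR must vanish with content; an ordinary least-squares fit
#' with a free intercept is available for sensitivity analysis) and
#' extrapolates to the atom count at which SNR reaches `threshold`:
#' `lod_atoms = threshold / slope` (through-origin) or
#' `(threshold - intercept) / slope`.  Given a per-cell loading the LOD is also
#' expressed in cells.
#'
#' @param atoms 19F atom counts of the standards (>= 3, all positive).
#' @param snr Measured SNR of each standard.
#' @param threshold SNR defining the LOD (2 by default).
#' @param loading Optional [cell_loading()]; when supplied `lod_cells =
#'   lod_atoms / loading$mean_atoms_per_cell`.
#' @param intercept Fit a free intercept instead of forcing the origin.
#' @param probe Optional label (e.g. `"5mm"`) carried into the result.
#' @return An object of class `lod_result` with `slope`, `lod_atoms`,
#'   `lod_cells` and `fit_diagnostics` (R squared and residual summary).
#' @export
estimate_lod <- function(atoms, snr, threshold = 2, loading = NULL,
                         intercept = FALSE, probe = NA_character_) {
  if (length(atoms) < 3) {
    stop("at least 3 calibration points are required", call. = FALSE)
  }
  if (any(!is.finite(atoms)) || any(atoms <= 0)) {
    stop("`atoms` must all be strictly positive", call. = FALSE)
  }
  if (length(snr) != length(atoms)) {
    stop("`atoms` and `snr` lengths differ", call. = FALSE)
  }
  fit <- if (intercept) stats::lm(snr ~ atoms) else stats::lm(snr ~ atoms - 1)
  co <- stats::coef(fit)
  slope <- unname(co[["atoms"]])
  b0 <- if (intercept) unname(co[["(Intercept)"]]) else 0
  if (!is.finite(slope) || slope <= 0) {
    stop("no detectable signal trend (non-positive fitted slope)",
         call. = FALSE)
  }
  lod_atoms <- (threshold - b0) / slope
  lod_cells <- if (!is.null(loading)) {
    stopifnot(inherits(loading, "cell_loading"))
    lod_atoms / loading$mean_atoms_per_cell
  } else {
    NA_real_
  }
  ss_tot <- sum((snr - if (intercept) mean(snr) else 0)^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(probe = probe, slope = slope, intercept = b0, threshold = threshold,
         lod_atoms = lod_atoms, lod_cells = lod_cells,
         fit_diagnostics = list(r_squared = r2,
                                residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                                n = length(atoms))),
    class = "lod_result"
  )
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result>%s SNR threshold %g: %.4g atoms%s (slope %.4g SNR/atom, R2 %.4f)\n",
              if (is.na(x$probe)) "" else paste0(" [", x$probe, "]"),
              x$threshold, x$lod_atoms,
              if (is.na(x$lod_cells)) "" else sprintf(" = %.3g cells", x$lod_cells),
              x$slope, x$fit_diagnostics$r_squared))
  invisible(x)
}

#' Default quantification configuration
#'
#' Collects the processing and quantification settings used by
#' [quantify_sample()] and [quantify_study()]: integration windows (+/- 1.5 ppm
#' around the tracer and reference peaks), a signal-free noise region
#' (-120 to -110 ppm, at least 30 linewidths from both peaks at the simulated
#' T2*), zero-fill and apodization, baseline polynomial order, the SNR
#' threshold below which a sample is flagged below the limit of detection, the
#' reference capillary and the per-cell loading.
#'
#' @param pfc_window,tfa_window,noise_region [peak_window()]s.
#' @param ref_capillary A [reference_capillary()].
#' @param loading A [cell_loading()].
#' @param injected_cells Nominal infused cell number (for percent injected
#'   dose); `NA` disables %ID columns.
#' @param snr_threshold SNR below which a sample is flagged `below_lod`.
#' @param zero_fill_factor,apodization_lb,poly_order Processing settings.
#' @param phase `"auto"` applies [auto_phase()] (local search); `"none"` skips
#'   phasing.
#' @param calibrate Recalibrate the ppm axis on the reference peak.
#' @param local_baseline Apply the per-window linear (bias/slope) correction in
#'   [integrate_peak()]; keeps far-tail leakage from the intense reference out
#'   of the tracer window.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(pfc_window = peak_window(-91.58, 1.5),
                         tfa_window = peak_window(-76, 1.5),
                         noise_region = peak_window(-115, 5),
                         ref_capillary = reference_capillary(),
                         loading = cell_loading(2e11, 0.5e11, 3L),
                         injected_cells = 2e7,
                         snr_threshold = 2,
                         zero_fill_factor = 2,
                         apodization_lb = 0,
                         poly_order = 1,
                         phase = c("auto", "none"),
                         calibrate = TRUE,
                         local_baseline = TRUE) {
  phase <- match.arg(phase)
  structure(
    list(pfc_window = pfc_window, tfa_window = tfa_window,
         noise_region = noise_region, ref_capillary = ref_capillary,
         loading = loading, injected_cells = injected_cells,
         snr_threshold = snr_threshold, zero_fill_factor = zero_fill_factor,
         apodization_lb = apodization_lb, poly_order = poly_order,
         phase = phase, calibrate = calibrate,
         local_baseline = local_baseline),
    class = "quant_config"
  )
}

#' Process and quantify one FID
#'
#' Runs the full single-sample pipeline: Fourier transform, automatic phasing,
#' polynomial baseline correction (excluding both peak windows), ppm
#' calibration on the reference peak, peak integration with noise-propagated
#' errors, and conversion to 19F atoms, apparent cells and percent injected
#' dose.  Samples are flagged `below_lod` (reported, not zeroed) when the
#' tracer peak's baseline-corrected centre height falls below
#' `config$snr_threshold` times the noise RMS.  The centre-height statistic is
#' used for the flag because it is unbiased in the absence of signal, whereas
#' the reported max-statistic SNR (`snr` column, the convention used on strong
#' calibration standards) picks up the maximum of the noise across the window
#' and so never drops to zero.
#'
#' @param fid A [new_fid()].
#' @param config A [quant_config()].
#' @return A one-row data.frame with columns `f19_atoms`, `f19_se`,
#'   `apparent_cells`, `cells_se`, `percent_id`, `percent_id_se`, `snr`,
#'   `below_lod`.
#' @export
quantify_sample <- function(fid, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  spec <- fid_to_spectrum(fid, config$zero_fill_factor, config$apodization_lb)
  if (config$phase == "auto") {
    spec <- auto_phase(spec, windows = list(config$pfc_window,
                                            config$tfa_window),
                       search = "local")
  }
  spec <- baseline_correct(spec,
                           list(config$pfc_window, config$tfa_window),
                           config$poly_order)
  if (config$calibrate) {
    spec <- calibrate_ppm(spec, reference_true = config$tfa_window$center,
                          reference_window = config$tfa_window,
                          noise_region = config$noise_region)
  }
  pfc <- integrate_peak(spec, config$pfc_window, config$noise_region,
                        local_baseline = config$local_baseline)
  ref <- integrate_peak(spec, config$tfa_window, config$noise_region,
                        local_baseline = config$local_baseline)
  content <- f19_content(pfc, ref, reference_atoms(config$ref_capillary))
  cells <- apparent_cell_number(content$atoms, config$loading, content$se)
  snr <- compute_snr(spec, config$pfc_window, config$noise_region)
  snr_flag <- center_height_snr(spec, config$pfc_window, config$noise_region,
                                local_baseline = config$local_baseline)
  pid <- pid_se <- NA_real_
  if (is.finite(config$injected_cells)) {
    pid <- percent_injected_dose(content$atoms, config$injected_cells,
                                 config$loading)
    pid_se <- if (content$atoms != 0) abs(pid) * content$se / abs(content$atoms)
              else percent_injected_dose(content$se, config$injected_cells,
                                         config$loading)
  }
  data.frame(
    f19_atoms = content$atoms, f19_se = content$se,
    apparent_cells = cells$cells, cells_se = cells$se,
    percent_id = pid, percent_id_se = pid_se,
    snr = snr, below_lod = snr_flag < config$snr_threshold
  )
}

#' Quantify every sample of a simulated (or assembled) study dataset
#'
#' Maps [quantify_sample()] over `dataset$samples` and binds the sample
#' metadata (mouse, group, timepoint, organ, mass, pooling) to the derived
#' quantities, yielding the biodistribution table consumed by
#' [biodistribution_report()].
#'
#' @param dataset A `study_dataset` from [simulate_study()].
#' @param config A [quant_config()]; by default the loading and injected dose
#'   are taken from the dataset's design.
#' @return A data.frame of biodistribution records, one row per sample.
#' @export
quantify_study <- function(dataset, config = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(config)) {
    config <- quant_config(
      ref_capillary = dataset$design$ref_capillary,
      loading = cell_loading(dataset$design$loading_atoms_per_cell),
      injected_cells = dataset$design$injected_cells
    )
  }
  rows <- lapply(dataset$samples, function(s) {
    q <- quantify_sample(s$fid, config)
    cbind(
      data.frame(sample_id = s$sample_id, mouse_id = s$mouse_id,
                 group = s$group, timepoint_d = s$timepoint_d, organ = s$organ,
                 mass_g = s$mass_g, pooled_n = s$pooled_n,
                 stringsAsFactors = FALSE),
      q
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
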