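# Quantification: reference atoms, contents, loadings, cell numbers, LOD

test_that("reference_atoms reproduces the hand-computed aliquot content", {
  # 0.1% w/v sodium-TFA, 50 ul: 0.05 mg / 136.01 g/mol * N_A * 3 F
  cap <- reference_capillary("sodium-TFA", mass_fraction = 0.1,
                             volume_ul = 50)
  oracle <- 5e-5 / 136.01 * 6.022e23 * 3
  expect_equal(reference_atoms(cap), oracle, tolerance = 1e-12)
  expect_equal(oracle, 6.64e17, tolerance = 0.001)

  # linearity in volume; zero mass fraction -> zero atoms
  cap2 <- reference_capillary("sodium-TFA", volume_ul = 100)
  expect_equal(reference_atoms(cap2), 2 * reference_atoms(cap))
  expect_equal(reference_atoms(reference_capillary(mass_fraction = 0)), 0)

  # unmatched T1 triggers the warning
  expect_warning(reference_capillary(T1 = 1.2), "differs from tracer T1")
})

test_that("f19_content applies the integral ratio with error propagation", {
  I <- function(v, se) structure(list(value = v, noise_se = se, n_points = 10L),
                                 class = "integral_result")
  # unit ratio returns the reference atoms
  expect_equal(f19_content(I(2, 0), I(2, 0), 6.64e17)$atoms, 6.64e17)
  r <- f19_content(I(1, 0.02), I(2, 0.01), 6.64e17)
  expect_equal(r$atoms, 3.32e17)
  expect_equal(r$se, 3.32e17 * sqrt((0.02 / 1)^2 + (0.01 / 2)^2),
               tolerance = 1e-12)
  expect_error(f19_content(I(1, 0), I(1, 0.5), 1), "reference peak unreliable")
})

test_that("per-cell loading and apparent cells reproduce the worked values", {
  # 3.0e17 atoms over 1.5e6 cells -> 2.0e11 atoms/cell
  ld <- per_cell_loading(3.0e17, 1.5e6)
  expect_equal(ld$mean_atoms_per_cell, 2.0e11)
  # equal replicates -> zero SE; loading of zero content is zero
  ld3 <- per_cell_loading(c(3e17, 3e17, 3e17), 1.5e6)
  expect_equal(ld3$se, 0)
  expect_equal(ld3$n_replicates, 3L)
  expect_equal(per_cell_loading(0, 1e6)$mean_atoms_per_cell, 0)
  expect_error(per_cell_loading(1e17, 0), "positive")

  # 1.7e16 atoms at 2e11 atoms/cell -> 85,000 apparent cells
  ac <- apparent_cell_number(1.7e16, cell_loading(2e11))
  expect_equal(ac$cells, 85000)
  expect_equal(apparent_cell_number(0, cell_loading(2e11))$cells, 0)
  # SE combines content and loading errors in quadrature
  ac2 <- apparent_cell_number(1.7e16, cell_loading(2e11, 0.5e11), 1.7e15)
  expect_equal(ac2$se, 85000 * sqrt(0.1^2 + 0.25^2), tolerance = 1e-12)
  # optional division correction doubles per interval
  ac3 <- apparent_cell_number(1.7e16, cell_loading(2e11),
                              division_corrected = TRUE, hours = 48,
                              division_interval_h = 24)
  expect_equal(ac3$cells, 85000 * 4)
})

test_that("percent injected dose and tail-corrected dose are plain arithmetic", {
  ld <- cell_loading(2e11)
  expect_equal(percent_injected_dose(2e7 * 2e11, 2e7, ld), 100)
  expect_equal(percent_injected_dose(0, 2e7, ld), 0)
  expect_equal(percent_injected_dose(0.15 * 4e18, 2e7, ld), 15)

  expect_equal(effective_iv_dose(2e7, ld, 0), 2e7)
  expect_equal(effective_iv_dose(2e7, ld, 0.1 * 2e7 * 2e11), 0.9 * 2e7)
  expect_error(effective_iv_dose(2e7, ld, 1.1 * 2e7 * 2e11), "exceeds")
})

test_that("estimate_lod extrapolates SNR = threshold and reproduces 7e3 cells", {
  # exact through-origin data with slope 2/1.4e15
  atoms <- c(1, 2, 4, 8) * 1e16
  snr <- 2 / 1.4e15 * atoms
  lod <- estimate_lod(atoms, snr, threshold = 2, loading = cell_loading(2e11))
  expect_equal(lod$lod_atoms, 1.4e15, tolerance = 1e-12)
  expect_equal(lod$lod_cells, 7e3, tolerance = 1e-12)
  expect_equal(lod$fit_diagnostics$r_squared, 1)

  # scale covariance: scaling all SNR by c scales lod_atoms by 1/c
  lod2 <- estimate_lod(atoms, 3 * snr, threshold = 2)
  expect_equal(lod2$lod_atoms, lod$lod_atoms / 3, tolerance = 1e-12)

  # free-intercept variant on shifted data
  lod3 <- estimate_lod(atoms, snr + 1, threshold = 2, intercept = TRUE)
  expect_equal(lod3$lod_atoms, (2 - 1) / (2 / 1.4e15), tolerance = 1e-6)

  # noisy calibration: median absolute error < 15% over 100 seeds
  errs <- vapply(1:100, function(k) {
    set.seed(k)
    snr_noisy <- snr * (1 + stats::rnorm(length(snr), 0, 0.1))
    estimate_lod(atoms, snr_noisy, threshold = 2)$lod_atoms / 1.4e15 - 1
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 0.15)

  expect_error(estimate_lod(atoms[1:2], snr[1:2]), "3 calibration points")
  expect_error(estimate_lod(atoms, -snr), "non-positive fitted slope")
})

test_that("quantification recovers simulated ground truth end to end", {
  acq <- test_acq(n_points = 8192L, n_averages = 128L)
  cap <- reference_capillary()
  ra <- reference_atoms(cap)
  cfg <- quant_config(ref_capillary = cap, loading = cell_loading(2e11),
                      injected_cells = 2e7)
  # known content at high SNR recovered within 2%
  atoms <- 3.0e17
  sens <- 80 / (atoms / 1e15)
  sigma <- nmrcytometry:::noise_sigma_for_sensitivity(
    acq, test_pfc(atoms, acq), sens)
  q <- quantify_sample(two_line_fid(acq, atoms, ra, sigma, seed = 17), cfg)
  expect_lt(abs(q$f19_atoms / atoms - 1), 0.02)
  expect_false(q$below_lod)
  # apparent cells track the loading
  expect_equal(q$apparent_cells, q$f19_atoms / 2e11)

  # pooling: a pooled sample equals the sum of its constituents (noiseless)
  f1 <- two_line_fid(acq, 1e16, ra, 0)
  f2 <- two_line_fid(acq, 3e16, ra, 0)
  pooled <- new_fid(f1$data + f2$data - two_line_fid(acq, 0, ra, 0)$data, acq)
  cfg0 <- quant_config(ref_capillary = cap, loading = cell_loading(2e11),
                       injected_cells = 2e7, phase = "none")
  qs <- vapply(list(f1, f2, pooled), function(f)
    quantify_sample(f, cfg0)$f19_atoms, numeric(1))
  # additivity is limited only by each sample's own far-tail crosstalk
  # between the tracer and reference windows (~1e-4 relative)
  expect_equal(qs[3], qs[1] + qs[2], tolerance = 5e-4)
})

test_that("matched reference T1 makes quantification recycle-delay independent", {
  cap <- reference_capillary()
  ra <- reference_atoms(cap)
  cfg <- quant_config(ref_capillary = cap, loading = cell_loading(2e11),
                      injected_cells = 2e7)
  atoms <- 3e17
  rec <- function(tfa_T1) vapply(c(1.5, 5, 10), function(tr) {
    acq <- test_acq(n_points = 4096L, recycle_delay = tr)
    fid <- two_line_fid(acq, atoms, ra, noise_sigma = 1e-9, seed = 2,
                        tfa_T1 = tfa_T1)
    quantify_sample(fid, cfg)$f19_atoms / atoms
  }, numeric(1))
  matched <- rec(0.47)
  expect_lt(max(matched) - min(matched), 0.01)

  # mismatched T1 (2x) reproduces the analytic saturation-factor ratio;
  # comparing against the matched-T1 measurement cancels the (shared, small)
  # window-truncation bias of the compact test acquisition
  acq <- test_acq(n_points = 4096L, recycle_delay = 1.5)
  b_matched <- quantify_sample(
    two_line_fid(acq, atoms, ra, noise_sigma = 1e-9, seed = 2),
    cfg)$f19_atoms / atoms
  suppressWarnings({
    fid <- two_line_fid(acq, atoms, ra, noise_sigma = 1e-9, seed = 2,
                        tfa_T1 = 0.94)
  })
  b_mismatched <- quantify_sample(fid, cfg)$f19_atoms / atoms
  analytic <- steady_state_factor(1.5, 0.47) / steady_state_factor(1.5, 0.94)
  expect_lt(abs((b_mismatched / b_matched) / analytic - 1), 0.01)
})

test_that("samples at half the LOD are flagged below_lod", {
  acq <- test_acq(n_points = 4096L, n_averages = 128L)
  cap <- reference_capillary()
  ra <- reference_atoms(cap)
  cfg <- quant_config(ref_capillary = cap, loading = cell_loading(2e11),
                      injected_cells = 2e7, snr_threshold = 2)
  # sensitivity 2/1.4 per 1e15 atoms -> LOD at 1.4e15; simulate at half that
  atoms <- 0.7e15
  flagged <- vapply(1:40, function(k) {
    sigma <- nmrcytometry:::noise_sigma_for_sensitivity(
      acq, test_pfc(atoms, acq), 2 / 1.4)
    quantify_sample(two_line_fid(acq, atoms, ra, sigma, seed = 500 + k),
                    cfg)$below_lod
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
})

test_that("quantify_study emits one record per sample with metadata attached", {
  des <- study_design(groups = "CAR", n_mice_per_group = 2L,
                      timepoints_d = c(2), homing_jitter_cv = 0,
                      pooled_organs = "lymph_node")
  acq <- test_acq(n_points = 4096L, n_averages = 512L)
  # scale line widths with the compact acquisition
  des$pfc_T2_star <- 0.05 * t2_scale(acq)
  des$tfa_T2_star <- 0.08 * t2_scale(acq)
  ds <- simulate_study(des, acq, seed = 3)
  bio <- quantify_study(ds)
  expect_equal(nrow(bio), length(ds$samples))
  expect_true(all(c("mouse_id", "group", "organ", "f19_atoms",
                    "apparent_cells", "percent_id", "below_lod") %in%
                    names(bio)))
  # pooled lymph node row present once per group-timepoint
  expect_equal(sum(bio$organ == "lymph_node"), 1)
  expect_equal(bio$pooled_n[bio$organ == "lymph_node"], 2L)
  # strong organs recovered within 10% at these SNRs
  truth <- vapply(ds$samples, `[[`, numeric(1), "true_atoms")
  strong <- truth > 1e17
  expect_true(all(abs(bio$f19_atoms[strong] / truth[strong] - 1) < 0.1))
})
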