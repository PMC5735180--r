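# Spectral processing: transform, phasing, baseline, calibration, integration

test_that("fid_to_spectrum places lines correctly and handles degenerate input", {
  acq <- test_acq()
  # all-zero FID -> all-zero spectrum
  sp0 <- fid_to_spectrum(simulate_fid(acq, test_pfc(0, acq), 0))
  expect_true(all(sp0$intensity == 0))
  expect_true(all(diff(sp0$ppm) < 0))  # descending ppm axis

  # single noiseless line lands at its shift
  sp <- fid_to_spectrum(simulate_fid(acq, test_pfc(1e16, acq), 0))
  step <- abs(stats::median(diff(sp$ppm)))
  expect_lt(abs(sp$ppm[which.max(sp$intensity)] - (-91.58)), 1.5 * step)

  # apodization broadens the line by lb Hz
  fid <- simulate_fid(acq, test_pfc(1e16, acq), 0)
  lb <- 10
  f0 <- measure_fwhm_hz(fid_to_spectrum(fid, 4))
  f1 <- measure_fwhm_hz(fid_to_spectrum(fid, 4, apodization_lb = lb))
  expect_lt(abs((f1 - f0) - lb) / lb, 0.15)

  expect_error(fid_to_spectrum(structure(list(data = complex(0),
                                              acq = acq), class = "fid")),
               "empty FID")
})

test_that("auto_phase recovers applied phases and fixes already-phased spectra", {
  acq <- test_acq()
  fid <- simulate_fid(acq, list(test_pfc(3e17, acq), test_tfa(6.6e17, acq)),
                      noise_sigma_per_scan = 1e-6, seed = 3)
  sp <- fid_to_spectrum(fid)

  # fixed point: re-phasing an already-phased spectrum changes the phase at
  # each peak by less than a degree (phi0 and phi1 individually trade off
  # along the line through the two peak positions)
  st <- tail(auto_phase(sp, search = "local")$record, 1)[[1]]
  for (shift in c(-91.58, -76)) {
    x_pk <- (shift - acq$carrier_ppm) / acq$spectral_width
    expect_lt(abs(st$phi0 + st$phi1 * x_pk), 1)
  }
  expect_lt(angle_diff(st$phi0, 0), 2)
  expect_lt(abs(st$phi1), 3)

  # inverse recovery of random applied (phi0, phi1) within 2 degrees
  set.seed(21)
  for (k in 1:8) {
    p0 <- stats::runif(1, -179, 179)
    p1 <- stats::runif(1, -90, 90)
    rec <- tail(auto_phase(apply_phase(sp, p0, p1),
                           search = "global")$record, 1)[[1]]
    expect_lt(angle_diff(rec$phi0, -p0), 2)
    expect_lt(abs(rec$phi1 + p1), 2)
  }

  # pure noise completes, flagged low-signal
  fidn <- simulate_fid(acq, test_pfc(0, acq), noise_sigma_per_scan = 1,
                       seed = 4)
  recn <- auto_phase(fid_to_spectrum(fidn))
  expect_true(tail(recn$record, 1)[[1]]$low_signal)
})

test_that("phase-integral invariance: recovered integral is stable under input phase", {
  acq <- test_acq()
  fid <- simulate_fid(acq, test_pfc(1e16, acq), 0)
  sp <- fid_to_spectrum(fid)
  nr <- default_noise_region()
  win <- peak_window(-91.58, 1.5)
  ref_val <- integrate_peak(auto_phase(sp, search = "global"), win, nr)$value
  for (p0 in c(-120, 45, 170)) {
    val <- integrate_peak(auto_phase(apply_phase(sp, p0, 30),
                                     search = "global"), win, nr)$value
    expect_lt(abs(val / ref_val - 1), 0.005)
  }
})

test_that("baseline_correct removes polynomial baselines without touching peaks", {
  acq <- test_acq()
  win <- peak_window(-91.58, 1.5)
  nr <- default_noise_region()

  # a compactly-supported peak (no Lorentzian tails) on an exactly flat
  # baseline passes through unchanged
  spb <- fid_to_spectrum(simulate_fid(acq, test_pfc(0, acq), 0))
  bump <- exp(-((spb$ppm + 91.58) / 0.2)^2 / 2)
  spb$intensity <- spb$intensity + bump
  spb$complex <- spb$complex + bump
  spc <- baseline_correct(spb, list(win), poly_order = 1)
  expect_lt(max(abs(spc$intensity - spb$intensity)), 1e-10)

  # order-0 on a constant offset restores the off-peak mean to zero
  spo <- spb
  spo$intensity <- spo$intensity + 3
  spo$complex <- spo$complex + 3
  spo <- baseline_correct(spo, list(win), 0)
  off <- spo$intensity[abs(spo$ppm - (-91.58)) > 5]
  expect_lt(abs(mean(off)), 1e-8)

  # injected linear ramp on a real line: peak integral recovered within 1%
  sp <- fid_to_spectrum(simulate_fid(acq, test_pfc(1e16, acq), 0))
  ramp <- seq(-1, 1, length.out = length(sp$intensity)) * max(sp$intensity) / 50
  spr <- sp
  spr$intensity <- spr$intensity + ramp
  spr$complex <- spr$complex + ramp
  v0 <- integrate_peak(sp, win, nr)$value
  v1 <- integrate_peak(baseline_correct(spr, list(win), 1), win, nr)$value
  expect_lt(abs(v1 / v0 - 1), 0.01)

  wide <- peak_window(acq$carrier_ppm, acq$spectral_width * 0.45)
  expect_error(baseline_correct(sp, list(wide), 1), "80%")
})

test_that("calibrate_ppm shifts the axis onto the reference and rejects junk", {
  acq <- test_acq()
  fid <- two_line_fid(acq, 1e16, noise_sigma = 1e-5, seed = 9)
  sp <- fid_to_spectrum(fid)
  step <- abs(stats::median(diff(sp$ppm)))

  # identity when the axis is already correct
  spc <- calibrate_ppm(sp)
  expect_lt(abs(tail(spc$record, 1)[[1]]$shift), 1.5 * step)

  # a mis-set axis is pulled back: tracer lands at -91.58
  spm <- sp
  spm$ppm <- spm$ppm + 0.3
  spm <- calibrate_ppm(spm)
  i <- nmrcytometry:::window_index(spm, peak_window(-91.58, 1))
  expect_lt(abs(spm$ppm[i[which.max(spm$intensity[i])]] - (-91.58)),
            1.5 * step)

  # absent reference peak -> error via the SNR gate: noisy spectrum whose
  # reference window carries no signal at all
  fidn <- simulate_fid(acq, test_pfc(1e16, acq), noise_sigma_per_scan = 1e-3,
                       seed = 2)
  spn <- fid_to_spectrum(fidn)
  spn$intensity[nmrcytometry:::window_index(spn, peak_window(-76, 1.5))] <- 0
  expect_error(calibrate_ppm(spn, noise_region = default_noise_region()),
               "reference peak not found")

  # implausibly large shift -> error
  expect_error(calibrate_ppm(sp, observed = -91.58), "10 ppm")
})

test_that("windowed integral matches the Lorentzian arctan fraction", {
  acq <- test_acq(n_points = 8192L)
  t2 <- 0.05 * t2_scale(acq)
  fid <- simulate_fid(acq, test_pfc(1e16, acq), 0)
  sp <- fid_to_spectrum(fid, zero_fill_factor = 4)
  nr <- default_noise_region()
  fwhm_ppm <- 1 / (pi * t2) / acq$spectrometer_freq
  # "unit area" normalisation from a very wide window and its own closed form
  wide <- integrate_peak(sp, peak_window(-91.58, 40 * fwhm_ppm), nr)$value
  unit_area <- wide / ((2 / pi) * atan(80))
  for (w in c(1, 2, 5, 10)) {
    frac <- integrate_peak(sp, peak_window(-91.58, w * fwhm_ppm), nr)$value /
      unit_area
    expect_lt(abs(frac / ((2 / pi) * atan(2 * w)) - 1), 0.005,
              label = sprintf("W/FWHM = %g", w))
  }
})

test_that("integrals are linear and their noise SE is calibrated", {
  acq <- test_acq(n_points = 2048L)
  nr <- default_noise_region()
  win <- peak_window(-91.58, 1.5)
  spA <- fid_to_spectrum(simulate_fid(acq, test_pfc(1e16, acq), 0))
  spB <- fid_to_spectrum(simulate_fid(acq, test_tfa(5e16, acq), 0))
  spAB <- spA
  spAB$intensity <- 2 * spA$intensity + 3 * spB$intensity
  IA <- integrate_peak(spA, win, nr)$value
  IB <- integrate_peak(spB, win, nr)$value
  expect_equal(integrate_peak(spAB, win, nr)$value, 2 * IA + 3 * IB,
               tolerance = 1e-12)

  # zero spectrum -> zero value and zero SE
  sp0 <- fid_to_spectrum(simulate_fid(acq, test_pfc(0, acq), 0))
  I0 <- integrate_peak(sp0, win, nr)
  expect_identical(I0$value, 0)
  expect_identical(I0$noise_se, 0)

  # empirical SD of signal-free window integrals matches noise_se within 10%
  vals <- ses <- numeric(300)
  for (k in 1:300) {
    spn <- fid_to_spectrum(simulate_fid(acq, test_pfc(0, acq), 1,
                                        seed = 7000 + k))
    I <- integrate_peak(spn, win, nr)
    vals[k] <- I$value
    ses[k] <- I$noise_se
  }
  expect_lt(abs(stats::sd(vals) / mean(ses) - 1), 0.10)

  # signal-free integral is within 3 SE nearly always
  expect_gt(mean(abs(vals) < 3 * ses), 0.985)

  expect_error(integrate_peak(spA, win, peak_window(-92, 1)), "disjoint")
})

test_that("compute_snr is scale-invariant and rejects noiseless input", {
  acq <- test_acq(n_points = 2048L)
  nr <- default_noise_region()
  win <- peak_window(-91.58, 1.5)
  sp <- fid_to_spectrum(simulate_fid(acq, test_pfc(1e16, acq), 1e-4, seed = 1))
  s1 <- compute_snr(sp, win, nr)
  sp2 <- sp
  sp2$intensity <- sp$intensity * 7.3
  expect_equal(compute_snr(sp2, win, nr), s1, tolerance = 1e-12)

  # constructed SNR: peak height 10, noise sigma 1 (in spectrum units)
  snrs <- vapply(1:100, function(k) {
    spn <- fid_to_spectrum(simulate_fid(acq, test_pfc(0, acq), 1,
                                        seed = 300 + k))
    h <- 10 * sqrt(mean(spn$intensity[nmrcytometry:::window_index(spn, nr)]^2))
    spn$intensity[which.min(abs(spn$ppm + 91.58))] <-
      spn$intensity[which.min(abs(spn$ppm + 91.58))] + h
    compute_snr(spn, win, nr)
  }, numeric(1))
  expect_lt(abs(mean(snrs) / 10 - 1), 0.10)

  sp0 <- fid_to_spectrum(simulate_fid(acq, test_pfc(0, acq), 0))
  expect_error(compute_snr(sp0, win, nr), "SNR undefined")
})

test_that("replaying a processing record reproduces the spectrum bit-identically", {
  acq <- test_acq()
  fid <- two_line_fid(acq, 1e16, noise_sigma = 1e-5, seed = 31)
  cfgw <- list(peak_window(-91.58, 1.5), peak_window(-76, 1.5))
  sp <- fid_to_spectrum(fid, 2)
  sp <- auto_phase(sp, windows = cfgw, search = "local")
  sp <- baseline_correct(sp, cfgw, 1)
  sp <- calibrate_ppm(sp, noise_region = default_noise_region())
  replayed <- replay_processing(fid, sp$record)
  expect_identical(replayed$intensity, sp$intensity)
  expect_identical(replayed$ppm, sp$ppm)
})
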