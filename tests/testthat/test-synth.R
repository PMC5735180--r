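# Synthetic FID and study generator

test_that("steady-state factor matches the closed form and a Bloch recursion", {
  # full-relaxation limit and the T1-matching symmetry
  expect_equal(steady_state_factor(100 * 0.47, 0.47), 1, tolerance = 1e-12)
  expect_equal(steady_state_factor(1.5, 0.47), 1 - exp(-1.5 / 0.47),
               tolerance = 1e-12)
  expect_equal(steady_state_factor(1.5, 0.47) / steady_state_factor(1.5, 0.47),
               1)

  # independent oracle: iterate the Bloch recursion for longitudinal
  # magnetisation to steady state, for several TR/T1/flip combinations
  bloch_ss <- function(TR, T1, theta_deg) {
    th <- theta_deg * pi / 180
    E <- exp(-TR / T1)
    mz <- 1
    for (i in 1:10000) mz <- 1 - (1 - mz * cos(th)) * E
    mz * sin(th)
  }
  for (TR in c(0.3, 1.5, 5, 10)) {
    for (T1 in c(0.1, 0.47, 2)) {
      for (th in c(30, 60, 90)) {
        expect_equal(steady_state_factor(TR, T1, th), bloch_ss(TR, T1, th),
                     tolerance = 1e-10,
                     label = sprintf("TR=%g T1=%g theta=%g", TR, T1, th))
      }
    }
  }
  expect_error(steady_state_factor(0, 1), "positive")
  expect_error(steady_state_factor(1, -1), "positive")
  expect_error(steady_state_factor(1, 1, 200), "flip_angle")
})

test_that("simulate_fid produces the expected line position, width and scaling", {
  acq <- test_acq()
  # zero content, zero noise -> all-zero FID
  fid0 <- simulate_fid(acq, test_pfc(0, acq), 0)
  expect_true(all(fid0$data == 0))

  # peak position and FWHM against the analytic Lorentzian
  fid <- simulate_fid(acq, test_pfc(1e16, acq), 0)
  sp <- fid_to_spectrum(fid, zero_fill_factor = 4)
  step <- abs(stats::median(diff(sp$ppm)))
  expect_lt(abs(sp$ppm[which.max(sp$intensity)] - (-91.58)), 1.5 * step)
  fwhm_expected <- 1 / (pi * 0.05 * t2_scale(acq))
  expect_lt(abs(measure_fwhm_hz(sp) - fwhm_expected) / fwhm_expected, 0.05)

  # determinism: same seed, bit-identical output
  f1 <- two_line_fid(acq, 1e16, noise_sigma = 0.5, seed = 11)
  f2 <- two_line_fid(acq, 1e16, noise_sigma = 0.5, seed = 11)
  expect_identical(f1$data, f2$data)

  # a line outside the window errors (no aliasing modelled)
  expect_error(
    simulate_fid(acq, species_line("x", acq$carrier_ppm + 60, 1, 0.01, 1)),
    "outside the spectral window")
})

test_that("SNR grows as the square root of the number of averages", {
  nr <- default_noise_region()
  win <- peak_window(-91.58, 1.5)
  n_avg <- c(32L, 128L, 512L)
  acq0 <- test_acq(n_points = 2048L, n_averages = 128L)
  # noise set for SNR ~30 at 128 averages: well above the spectral tail floor,
  # well below the regime where the max-statistic bias matters
  sigma <- nmrcytometry:::noise_sigma_for_sensitivity(
    acq0, test_pfc(2e16, acq0), sensitivity = 2 / 1.4)
  mean_snr <- vapply(n_avg, function(na) {
    acq <- test_acq(n_points = 2048L, n_averages = na)
    snrs <- vapply(1:25, function(k) {
      fid <- simulate_fid(acq, test_pfc(2e16, acq),
                          noise_sigma_per_scan = sigma, seed = 100 + k)
      compute_snr(fid_to_spectrum(fid), win, nr)
    }, numeric(1))
    mean(snrs)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(mean_snr) ~ log(n_avg)))[[2]]
  expect_gt(slope, 0.45)
  expect_lt(slope, 0.55)
})

test_that("calibration series are linear in content and reproducible", {
  acq <- test_acq(n_points = 2048L, n_averages = 128L, recycle_delay = 10)
  counts <- c(1e16, 2e16, 4e16)
  line <- test_tfa(0, acq)
  s1 <- simulate_calibration_series(acq, counts, sensitivity = 2 / 1.4,
                                    seed = 5, line = line)
  s2 <- simulate_calibration_series(acq, counts, sensitivity = 2 / 1.4,
                                    seed = 5, line = line)
  expect_identical(lapply(s1, `[[`, "data"), lapply(s2, `[[`, "data"))

  # doubling content doubles the noiseless peak integral
  nr <- default_noise_region()
  win <- peak_window(-76, 1.5)
  ints <- vapply(seq_along(counts), function(i) {
    ln <- line
    ln$f19_atoms <- counts[i]
    integrate_peak(fid_to_spectrum(simulate_fid(acq, ln, 0)), win, nr)$value
  }, numeric(1))
  expect_equal(ints[2] / ints[1], 2, tolerance = 1e-6)
  expect_equal(ints[3] / ints[2], 2, tolerance = 1e-6)

  expect_error(simulate_calibration_series(acq, c(1e16, 2e16), 1, seed = 1),
               "3 calibration levels")
  expect_error(simulate_calibration_series(acq, c(1e16, 0, 2e16), 1, seed = 1),
               "strictly positive")
})

test_that("study bookkeeping conserves 19F and routes death flux to the liver", {
  # deterministic design: no death, no division effect on totals, no jitter
  des <- study_design(groups = c("CAR", "untransduced"),
                      n_mice_per_group = 3L, timepoints_d = c(2),
                      death_rate_per_day = 0, misinjection_fraction = 0,
                      homing_jitter_cv = 0)
  acq <- test_acq(n_points = 1024L)
  ds <- simulate_study(des, acq, seed = 1)
  inj <- des$injected_cells * des$loading_atoms_per_cell
  tot <- tapply(ds$truth$true_atoms, ds$truth$mouse_id, sum)
  expect_true(all(abs(tot / inj - 1) < 1e-12))

  # tail fraction exact
  des2 <- study_design(groups = "CAR", n_mice_per_group = 2L,
                       timepoints_d = c(2), misinjection_fraction = 0.1,
                       homing_jitter_cv = 0)
  ds2 <- simulate_study(des2, acq, seed = 1)
  tail_atoms <- ds2$truth$true_atoms[ds2$truth$organ == "tail"]
  expect_equal(tail_atoms,
               rep(0.1 * des2$injected_cells * des2$loading_atoms_per_cell,
                   length(tail_atoms)))

  # death routes label to liver: liver ground truth non-decreasing in time,
  # verified against stepping the bookkeeping by brute force
  des3 <- study_design(groups = "CAR", n_mice_per_group = 3L,
                       timepoints_d = c(2, 7, 14), death_rate_per_day = 0.08,
                       homing_jitter_cv = 0)
  ds3 <- simulate_study(des3, acq, seed = 1)
  liver <- ds3$truth[ds3$truth$organ == "liver", ]
  liver_by_t <- tapply(liver$true_atoms, liver$timepoint_d, mean)
  expect_true(all(diff(liver_by_t) > 0))
  # brute-force daily stepping oracle for the day-14 liver content
  fr <- with(des3$organ_fractions[des3$organ_fractions$group == "CAR", ],
             stats::setNames(fraction, organ))
  iv <- des3$injected_cells * des3$loading_atoms_per_cell *
    (1 - des3$misinjection_fraction)
  pools <- iv * fr
  liver_acc <- 0
  dt <- 1 / 64
  for (i in seq_len(14 * 64)) {
    died <- pools * des3$death_rate_per_day * dt
    pools <- pools - died
    liver_acc <- liver_acc + sum(died[names(died) != "liver"])
  }
  oracle_liver <- iv * fr[["liver"]] + liver_acc
  expect_equal(unname(liver_by_t["14"]), oracle_liver, tolerance = 2e-3)

  # identical (design, acq, seed) -> bit-identical datasets
  ds3b <- simulate_study(des3, acq, seed = 1)
  expect_identical(lapply(ds3$samples, `[[`, "fid"),
                   lapply(ds3b$samples, `[[`, "fid"))
  expect_identical(ds3$truth, ds3b$truth)

  # over-allocated fractions error
  bad_fr <- data.frame(group = "CAR", organ = c("liver", "spleen"),
                       fraction = c(0.7, 0.4))
  expect_error(study_design(organ_fractions = bad_fr), "sum")
})

test_that("division dilutes the per-cell label but conserves organ totals", {
  des <- study_design(groups = "CAR", n_mice_per_group = 2L,
                      timepoints_d = c(2, 14), death_rate_per_day = 0,
                      division_interval_h = 24, homing_jitter_cv = 0)
  ds <- simulate_study(des, test_acq(n_points = 1024L), seed = 1)
  tr <- ds$truth[ds$truth$organ == "spleen", ]
  atoms_by_t <- tapply(tr$true_atoms, tr$timepoint_d, mean)
  cells_by_t <- tapply(tr$true_cells, tr$timepoint_d, mean)
  expect_equal(unname(atoms_by_t["14"] / atoms_by_t["2"]), 1, tolerance = 1e-12)
  expect_equal(unname(cells_by_t["14"] / cells_by_t["2"]), 2^12,
               tolerance = 1e-9)  # 12 extra divisions at 24 h spacing
  per_cell <- tapply(tr$atoms_per_cell, tr$timepoint_d, mean)
  expect_equal(unname(per_cell["14"] / per_cell["2"]), 2^-12,
               tolerance = 1e-9)
})
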