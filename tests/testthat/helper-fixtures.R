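# Shared fixtures.  Unit tests mostly use a compact acquisition (fewer FID
# points) for speed; line T2* values are scaled down by the same factor so the
# acquisition time stays ~17 tracer T2* (as in the full protocol) and no
# truncation wiggles appear.

test_acq <- function(n_points = 4096L, n_averages = 32L, ...) {
  acquisition_params(n_points = n_points, n_averages = n_averages, ...)
}

t2_scale <- function(acq) acq$n_points / 32000

test_pfc <- function(atoms, acq) pfc_line(atoms, T2_star = 0.05 * t2_scale(acq))

test_tfa <- function(atoms, acq, T1 = 0.47) {
  tfa_line(atoms, T1 = T1, T2_star = 0.08 * t2_scale(acq))
}

default_noise_region <- function() peak_window(-115, 5)

# two-line sample FID: tracer + reference capillary
two_line_fid <- function(acq, pfc_atoms, ref_atoms = 6.64e17,
                         noise_sigma = 0, seed = NULL, tfa_T1 = 0.47) {
  simulate_fid(acq, list(test_pfc(pfc_atoms, acq),
                         test_tfa(ref_atoms, acq, T1 = tfa_T1)),
               noise_sigma_per_scan = noise_sigma, seed = seed)
}

# smallest angular difference in degrees
angle_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

measure_fwhm_hz <- function(spectrum) {
  # interpolate the half-height crossings so the measure is not quantised to
  # the axis grid
  y <- spectrum$intensity
  x <- spectrum$ppm
  half <- max(y) / 2
  p <- which.max(y)
  cross <- function(side) {
    i <- p
    while (y[i + side] > half) i <- i + side
    j <- i + side
    x[i] + (x[j] - x[i]) * (half - y[i]) / (y[j] - y[i])
  }
  abs(cross(-1L) - cross(1L)) * spectrum$acq$spectrometer_freq
}
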