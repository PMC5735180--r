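#' Steady-state saturation factor under repeated pulsing
#'
#' With a recycle delay TR short relative to T1, the longitudinal magnetisation
#' does not fully recover between scans and the per-scan signal is attenuated
#' by the standard steady-state factor
#' \deqn{f = (1 - E)\sin\theta / (1 - E\cos\theta), \quad E = e^{-TR/T1}.}
#' When the reference compound's T1 is matched to the tracer's (the MnCl2-doped
#' TFA capillary), the factors cancel in the integral ratio and quantification
#' is unbiased at any recycle delay.
#'
#' @param recycle_delay Recycle delay TR in seconds (> 0).
#' @param T1 Longitudinal relaxation time in seconds (> 0).
#' @param flip_angle Flip angle in degrees, in (0, 180].
#' @return The per-scan attenuation factor in (0, 1]; tends to 1 as
#'   TR/T1 grows at a 90 degree flip.
#' @export
steady_state_factor <- function(recycle_delay, T1, flip_angle = 90) {
  if (!all(is.finite(recycle_delay)) || any(recycle_delay <= 0)) {
    stop("`recycle_delay` must be positive", call. = FALSE)
  }
  if (!all(is.finite(T1)) || any(T1 <= 0)) {
    stop("`T1` must be positive", call. = FALSE)
  }
  if (any(flip_angle <= 0) || any(flip_angle > 180)) {
    stop("`flip_angle` must be in (0, 180] degrees", call. = FALSE)
  }
  E <- exp(-recycle_delay / T1)
  theta <- flip_angle * pi / 180
  (1 - E) * sin(theta) / (1 - E * cos(theta))
}

#' Simulate a free induction decay
#'
#' Builds a noisy, averaged FID from a set of resonance lines:
#' \deqn{s(t) = \sum_k A_k f_k e^{(i 2\pi \Delta f_k - 1/T2^*_k) t} + \epsilon(t)}
#' where \eqn{A_k = gain \cdot n_{avg} \cdot f19\_atoms_k}, \eqn{f_k} is the
#' steady-state saturation factor for line k at the acquisition's recycle delay
#' and flip angle, and \eqn{\Delta f_k} is the offset from the carrier in Hz.
#' Averaging `n_averages` transients multiplies coherent signal by
#' `n_averages` and complex Gaussian noise by `sqrt(n_averages)`, so SNR grows
#' as the square root of the number of averages.
#'
#' The per-line amplitude is proportional to the number of 19F nuclei times an
#' arbitrary receiver `gain`; absolute atom counts are therefore only
#' recoverable through the internal reference, as in the physical experiment.
#'
#' @param acq An [acquisition_params()] object.
#' @param lines A list of [species_line()] objects (a single line may be passed
#'   unwrapped).  Every shift must fall inside the spectral window; no aliasing
#'   is modelled.
#' @param noise_sigma_per_scan Per-scan standard deviation of each quadrature
#'   noise component, in signal units.
#' @param seed Integer seed; the same `(acq, lines, noise, seed)` quadruple
#'   yields a bit-identical FID.  `NULL` draws from the current RNG stream.
#' @param gain Receiver gain (signal units per 19F atom per scan).
#' @return A [new_fid()] object.
#' @export
simulate_fid <- function(acq, lines, noise_sigma_per_scan = 0, seed = NULL,
                         gain = 1e-15) {
  stopifnot(inherits(acq, "acq_params"))
  if (inherits(lines, "species_line")) lines <- list(lines)
  lo <- acq$carrier_ppm - acq$spectral_width / 2
  hi <- acq$carrier_ppm + acq$spectral_width / 2
  for (ln in lines) {
    if (!inherits(ln, "species_line")) {
      stop("`lines` must be species_line objects", call. = FALSE)
    }
    if (ln$shift < lo || ln$shift > hi) {
      stop(sprintf("line '%s' at %.2f ppm lies outside the spectral window [%g, %g] ppm",
                   ln$name, ln$shift, lo, hi), call. = FALSE)
    }
  }
  n <- acq$n_points
  t <- (seq_len(n) - 1) * dwell_s(acq)
  signal <- complex(real = numeric(n), imaginary = numeric(n))
  for (ln in lines) {
    if (ln$f19_atoms == 0) next
    amp <- gain * ln$f19_atoms * acq$n_averages *
      steady_state_factor(acq$recycle_delay, ln$T1, acq$flip_angle)
    df <- (ln$shift - acq$carrier_ppm) * acq$spectrometer_freq  # Hz
    signal <- signal + amp * exp((2i * pi * df - 1 / ln$T2_star) * t)
  }
  if (noise_sigma_per_scan > 0) {
    sd_pt <- noise_sigma_per_scan * sqrt(acq$n_averages)
    noise_fun <- function() {
      complex(real = stats::rnorm(n, 0, sd_pt),
              imaginary = stats::rnorm(n, 0, sd_pt))
    }
    noise <- if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
    signal <- signal + noise
  }
  new_fid(signal, acq, seed_record = seed)
}

# Cache of noiseless processed peak heights used to translate an SNR
# sensitivity (SNR per 1e15 atoms) into a time-domain noise sigma.
.height_cache <- new.env(parent = emptyenv())

# Processed absorption peak height for a single line carrying 1e15 19F atoms,
# under default processing (zero-fill 2, no apodization).  Cached.
peak_height_per_1e15 <- function(acq, line, gain = 1e-15) {
  key <- paste(acq$spectrometer_freq, acq$spectral_width, acq$n_points,
               acq$n_averages, acq$recycle_delay, acq$flip_angle,
               line$shift, line$T1, line$T2_star, gain, sep = "|")
  if (!is.null(.height_cache[[key]])) return(.height_cache[[key]])
  ln <- line
  ln$f19_atoms <- 1e15
  fid <- simulate_fid(acq, list(ln), noise_sigma_per_scan = 0, gain = gain)
  spec <- fid_to_spectrum(fid)
  win <- peak_window(ln$shift, 1.5)
  idx <- window_index(spec, win)
  h <- max(Re(spec$complex[idx]))
  .height_cache[[key]] <- h
  h
}

# Time-domain per-scan noise sigma that yields, after default processing, an
# expected peak SNR of `sensitivity` (SNR per 1e15 atoms at `ref_averages`
# averages) for the given line.  Frequency-domain noise RMS per quadrature is
# sigma_t * dt * sqrt(n_averages * n_points) for the dt-scaled DFT.
noise_sigma_for_sensitivity <- function(acq, line, sensitivity,
                                        ref_averages = 128, gain = 1e-15) {
  if (!is.finite(sensitivity) || sensitivity <= 0) {
    stop("`sensitivity` must be positive", call. = FALSE)
  }
  h15 <- peak_height_per_1e15(acq, line, gain = gain)
  target_rms <- h15 / (sensitivity * sqrt(acq$n_averages / ref_averages))
  target_rms / (dwell_s(acq) * sqrt(acq$n_averages * acq$n_points))
}

#' Simulate a calibration dilution series
#'
#' Emulates the limit-of-detection protocol: standards of known, strictly
#' increasing 19F content (serial TFA dilutions) acquired under identical
#' conditions, so the processed SNR is proportional to the atom count.  The
#' noise level is set so a standard carrying 1e15 atoms has an expected SNR of
#' `sensitivity` at `ref_averages` averages (SNR scales with the square root of
#' the actual number of averages).
#'
#' @param acq An [acquisition_params()] object (the LOD protocol used 128
#'   averages and a 10 s recycle delay).
#' @param atom_counts Numeric vector (>= 3 levels, all positive) of 19F atom
#'   counts, one per standard.
#' @param sensitivity Expected SNR per 1e15 atoms at `ref_averages` averages.
#' @param seed Integer seed; level i uses `derive_seed(seed, i)`.
#' @param line Template [species_line()] for the standards (default TFA).
#' @param ref_averages Number of averages at which `sensitivity` is defined.
#' @param gain Receiver gain.
#' @return A list of [new_fid()] objects with an `atom_counts` attribute.
#' @export
simulate_calibration_series <- function(acq, atom_counts, sensitivity, seed,
                                        line = tfa_line(0), ref_averages = 128,
                                        gain = 1e-15) {
  if (length(atom_counts) < 3) {
    stop("at least 3 calibration levels are required", call. = FALSE)
  }
  if (any(!is.finite(atom_counts)) || any(atom_counts <= 0)) {
    stop("`atom_counts` must all be strictly positive", call. = FALSE)
  }
  sigma <- noise_sigma_for_sensitivity(acq, line, sensitivity,
                                       ref_averages = ref_averages, gain = gain)
  fids <- vector("list", length(atom_counts))
  for (i in seq_along(atom_counts)) {
    ln <- line
    ln$f19_atoms <- atom_counts[i]
    fids[[i]] <- simulate_fid(acq, list(ln), noise_sigma_per_scan = sigma,
                              seed = derive_seed(seed, i), gain = gain)
  }
  attr(fids, "atom_counts") <- atom_counts
  attr(fids, "sensitivity") <- sensitivity
  fids
}
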