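#' Acquisition parameters for a 1D 19F NMR experiment
#'
#' Bundles the pulse-and-acquire settings used both by the synthetic FID
#' generator and by the spectral processing (which needs the spectral width,
#' carrier and spectrometer frequency to build the ppm axis).  Defaults mirror
#' a 9.4 T (400 MHz 1H) spectrometer acquiring 19F at 376.5 MHz with a 100 ppm
#' window and 32,000 complex points.
#'
#' @param spectrometer_freq 19F Larmor frequency in MHz.
#' @param spectral_width Spectral width in ppm.
#' @param n_points Number of complex FID points.
#' @param n_averages Number of averaged transients (scans).
#' @param recycle_delay Inter-scan recycle delay in seconds.  Together with the
#'   T1 of each species this sets the steady-state saturation factor; see
#'   [steady_state_factor()].
#' @param pulse_width Excitation pulse width in microseconds (metadata only).
#' @param flip_angle Excitation flip angle in degrees.
#' @param carrier_ppm Centre of the spectral window in ppm.  The default (-85)
#'   places both the PFC (-91.58 ppm) and TFA (-76 ppm) resonances well inside
#'   a 100 ppm window.
#'
#' @return An object of class `acq_params`.
#' @export
acquisition_params <- function(spectrometer_freq = 376.5,
                               spectral_width = 100,
                               n_points = 32000L,
                               n_averages = 32L,
                               recycle_delay = 1.5,
                               pulse_width = 17,
                               flip_angle = 90,
                               carrier_ppm = -85) {
  n_points <- as.integer(n_points)
  n_averages <- as.integer(n_averages)
  if (is.na(n_points) || n_points <= 0L) {
    stop("`n_points` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(spectral_width) || spectral_width <= 0) {
    stop("`spectral_width` must be positive (ppm)", call. = FALSE)
  }
  if (is.na(n_averages) || n_averages < 1L) {
    stop("`n_averages` must be >= 1", call. = FALSE)
  }
  if (!is.finite(recycle_delay) || recycle_delay <= 0) {
    stop("`recycle_delay` must be positive (s)", call. = FALSE)
  }
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0) {
    stop("`spectrometer_freq` must be positive (MHz)", call. = FALSE)
  }
  structure(
    list(
      spectrometer_freq = spectrometer_freq,
      spectral_width = spectral_width,
      n_points = n_points,
      n_averages = n_averages,
      recycle_delay = recycle_delay,
      pulse_width = pulse_width,
      flip_angle = flip_angle,
      carrier_ppm = carrier_ppm
    ),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> %g MHz 19F, %g ppm sw, %d pts, %d avg, TR %g s, carrier %g ppm\n",
    x$spectrometer_freq, x$spectral_width, x$n_points, x$n_averages,
    x$recycle_delay, x$carrier_ppm
  ))
  invisible(x)
}

# spectral width in Hz
sw_hz <- function(acq) acq$spectral_width * acq$spectrometer_freq

# dwell time in seconds
dwell_s <- function(acq) 1 / sw_hz(acq)

#' A single 19F resonance line
#'
#' Describes one resonance used by the FID simulator: its chemical shift,
#' longitudinal relaxation time T1 (governs saturation under repeated pulsing
#' at short recycle delay), effective transverse decay T2* (sets the Lorentzian
#' full width at half maximum, FWHM = 1 / (pi * T2*)), and how many 19F nuclei
#' contribute to it.
#'
#' @param name Label, e.g. `"PFC"` or `"TFA"`.
#' @param shift Chemical shift in ppm.
#' @param T1 Longitudinal relaxation time in seconds.
#' @param T2_star Effective transverse relaxation time in seconds.
#' @param f19_atoms Number of contributing 19F nuclei (may be 0).
#'
#' @return An object of class `species_line`.
#' @export
species_line <- function(name, shift, T1, T2_star, f19_atoms) {
  if (!is.finite(T1) || T1 <= 0) stop("`T1` must be positive", call. = FALSE)
  if (!is.finite(T2_star) || T2_star <= 0) {
    stop("`T2_star` must be positive", call. = FALSE)
  }
  if (!is.finite(f19_atoms) || f19_atoms < 0) {
    stop("`f19_atoms` must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name, shift = shift, T1 = T1, T2_star = T2_star,
         f19_atoms = f19_atoms),
    class = "species_line"
  )
}

#' Default PFC tracer line (CS-1000-like single dominant resonance)
#'
#' The perfluorocarbon tracer is modelled as one dominant line at -91.58 ppm
#' with T1 = 0.47 s at 9.4 T; quantification uses only this peak.
#'
#' @param f19_atoms Number of 19F nuclei in the sample.
#' @param T2_star Effective transverse relaxation time in seconds.
#' @return A [species_line()].
#' @export
pfc_line <- function(f19_atoms, T2_star = 0.05) {
  species_line("PFC", shift = -91.58, T1 = 0.47, T2_star = T2_star,
               f19_atoms = f19_atoms)
}

#' Default TFA reference line
#'
#' Trifluoroacetate reference at -76 ppm.  In the ex vivo protocol the sealed
#' capillary is doped with MnCl2 so the TFA T1 matches the tracer's (~0.47 s);
#' matched T1 makes the integral ratio independent of the recycle delay.
#'
#' @param f19_atoms Number of 19F nuclei in the reference.
#' @param T1 Longitudinal relaxation time in seconds (0.47 when T1-matched).
#' @param T2_star Effective transverse relaxation time in seconds.
#' @return A [species_line()].
#' @export
tfa_line <- function(f19_atoms, T1 = 0.47, T2_star = 0.08) {
  species_line("TFA", shift = -76, T1 = T1, T2_star = T2_star,
               f19_atoms = f19_atoms)
}

#' Construct a free induction decay object
#'
#' @param data Complex vector of length `acq$n_points`.
#' @param acq An [acquisition_params()] object.
#' @param seed_record Integer seed used to generate the FID, or `NULL`.
#' @return An object of class `fid`.
#' @export
new_fid <- function(data, acq, seed_record = NULL) {
  stopifnot(inherits(acq, "acq_params"))
  if (length(data) != acq$n_points) {
    stop("FID length does not match `acq$n_points`", call. = FALSE)
  }
  structure(
    list(data = as.complex(data), acq = acq, seed_record = seed_record),
    class = "fid"
  )
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("<fid> %d complex points, %d averages, seed %s\n",
              length(x$data), x$acq$n_averages,
              if (is.null(x$seed_record)) "none" else x$seed_record))
  invisible(x)
}

# --- seeding -----------------------------------------------------------------

#' Derive a per-sample seed from a top-level seed and a counter
#'
#' All randomness in the package flows from one top-level seed; sub-tasks
#' (each FID, each mouse) use seeds derived by this fixed counter scheme, so a
#' subset of a dataset can be regenerated without simulating the rest.
#'
#' @param seed Top-level integer seed.
#' @param counter Non-negative integer index of the sub-task.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + counter * 9973) %%
               2147483647)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
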