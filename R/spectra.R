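#' Integration window on the ppm axis
#'
#' @param center Window centre in ppm.
#' @param half_width Half width in ppm (> 0).
#' @return An object of class `peak_window`.
#' @export
peak_window <- function(center, half_width) {
  if (!is.finite(half_width) || half_width <= 0) {
    stop("`half_width` must be positive", call. = FALSE)
  }
  structure(list(center = center, half_width = half_width),
            class = "peak_window")
}

# Indices of spectrum points falling inside a window; errors if the window is
# not fully inside the axis range.
window_index <- function(spectrum, window, partial = FALSE) {
  ppm <- spectrum$ppm
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  if (!partial && (lo < min(ppm) || hi > max(ppm))) {
    stop(sprintf("window [%g, %g] ppm extends outside the axis [%g, %g] ppm",
                 lo, hi, min(ppm), max(ppm)), call. = FALSE)
  }
  which(ppm >= lo & ppm <= hi)
}

# fftshift for even-length vectors
fft_shift <- function(x) {
  m <- length(x)
  h <- m %/% 2
  c(x[(h + 1):m], x[1:h])
}

new_spectrum <- function(cplx, ppm, acq, record, zero_fill_factor) {
  structure(
    list(complex = cplx, intensity = Re(cplx), ppm = ppm, acq = acq,
         record = record, zero_fill_factor = zero_fill_factor),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  steps <- vapply(x$record, function(s) s$step, character(1))
  cat(sprintf("<nmr_spectrum> %d points, %.2f to %.2f ppm; steps: %s\n",
              length(x$intensity), max(x$ppm), min(x$ppm),
              paste(steps, collapse = " -> ")))
  invisible(x)
}

#' Fourier transform an FID into a frequency-domain spectrum
#'
#' Applies optional exponential apodization, halves the first point (so the
#' discrete transform of a one-sided decay samples the continuous Lorentzian
#' without a DC offset), zero-fills, Fourier transforms and scales by the dwell
#' time.  With that scaling the spectrum approximates the continuous one-sided
#' Fourier transform of the FID: the absorption-mode integral of a noiseless,
#' unapodized line over the whole axis (in Hz) equals half its initial FID
#' amplitude.  Absolute scale is immaterial downstream because quantification
#' uses the ratio of two integrals from the same spectrum.
#'
#' The ppm axis is stored in descending order (high to low ppm, the standard
#' NMR display convention).  The complex spectrum is retained internally so
#' that phasing can follow.
#'
#' @param fid A [new_fid()] object.
#' @param zero_fill_factor Integer >= 1; the FID is padded to
#'   `zero_fill_factor * n_points` before transformation.
#' @param apodization_lb Exponential line broadening in Hz: the FID is
#'   multiplied by `exp(-pi * lb * t)`, which adds `lb` Hz to the Lorentzian
#'   FWHM.
#' @return An `nmr_spectrum` object.
#' @export
fid_to_spectrum <- function(fid, zero_fill_factor = 2, apodization_lb = 0) {
  stopifnot(inherits(fid, "fid"))
  if (length(fid$data) == 0) stop("empty FID", call. = FALSE)
  zero_fill_factor <- as.integer(zero_fill_factor)
  if (is.na(zero_fill_factor) || zero_fill_factor < 1) {
    stop("`zero_fill_factor` must be an integer >= 1", call. = FALSE)
  }
  acq <- fid$acq
  n <- acq$n_points
  dt <- dwell_s(acq)
  td <- fid$data
  if (apodization_lb > 0) {
    td <- td * exp(-pi * apodization_lb * (seq_len(n) - 1) * dt)
  }
  td[1] <- td[1] / 2
  m <- n * zero_fill_factor
  td <- c(td, complex(real = numeric(m - n), imaginary = numeric(m - n)))
  sp <- fft_shift(stats::fft(td)) * dt
  freq_hz <- (seq_len(m) - 1 - m / 2) * sw_hz(acq) / m
  ppm <- acq$carrier_ppm + freq_hz / acq$spectrometer_freq
  ord <- order(ppm, decreasing = TRUE)
  record <- list(list(step = "fid_to_spectrum",
                      zero_fill_factor = zero_fill_factor,
                      apodization_lb = apodization_lb))
  new_spectrum(sp[ord], ppm[ord], acq, record, zero_fill_factor)
}

# phase ramp over the axis; x runs from -0.5 to 0.5 across the spectral width,
# pivoted at the carrier
phase_vector <- function(spectrum, phi0, phi1) {
  x <- (spectrum$ppm - spectrum$acq$carrier_ppm) / spectrum$acq$spectral_width
  (phi0 + phi1 * x) * pi / 180
}

#' Apply zeroth- and first-order phase to a spectrum
#'
#' The first-order term is linear across the spectral window, pivoted at the
#' carrier: a point at the window edge receives `phi0 + phi1/2` degrees.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param phi0 Zeroth-order phase in degrees.
#' @param phi1 First-order phase in degrees across the full spectral width.
#' @return The phased spectrum (processing record extended).
#' @export
apply_phase <- function(spectrum, phi0, phi1 = 0) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  ph <- phase_vector(spectrum, phi0, phi1)
  cplx <- spectrum$complex * exp(1i * ph)
  spectrum$complex <- cplx
  spectrum$intensity <- Re(cplx)
  spectrum$record <- c(spectrum$record,
                       list(list(step = "apply_phase", phi0 = phi0, phi1 = phi1)))
  spectrum
}

# Straight line fitted to the flanking margins of a window (from 1 to
# 1 + flank half-widths on either side); NULL when too few flank points.
flank_line <- function(spectrum, window, flank = 2) {
  w <- window$half_width
  fl <- c(window_index(spectrum,
                       peak_window(window$center - (1 + flank / 2) * w,
                                   flank * w / 2), partial = TRUE),
          window_index(spectrum,
                       peak_window(window$center + (1 + flank / 2) * w,
                                   flank * w / 2), partial = TRUE))
  if (length(fl) < 8) return(NULL)
  fit <- stats::lm.fit(cbind(1, spectrum$ppm[fl]), spectrum$intensity[fl])
  list(coef = unname(fit$coefficients), n = length(fl))
}

# Peak height read at the window centre (mean of the 2k+1 nearest points,
# after removing the flank-fitted local baseline), over the noise RMS.
# Unlike the max-statistic SNR this is unbiased in the absence of signal, so
# it can drive the below-LOD flag.
center_height_snr <- function(spectrum, window, noise_region, k = 2L,
                              local_baseline = TRUE) {
  nidx <- window_index(spectrum, noise_region)
  rms <- sqrt(mean(spectrum$intensity[nidx]^2))
  if (rms == 0) stop("noiseless spectrum; SNR undefined", call. = FALSE)
  ic <- which.min(abs(spectrum$ppm - window$center))
  idx <- max(1L, ic - k):min(length(spectrum$ppm), ic + k)
  h <- spectrum$intensity[idx]
  if (local_baseline) {
    fit <- flank_line(spectrum, window, 2)
    if (!is.null(fit)) h <- h - (fit$coef[1] + fit$coef[2] * spectrum$ppm[idx])
  }
  mean(h) / rms
}

# negative-absorption penalty evaluated on a decimated point grid
phase_objective <- function(spectrum, idx) {
  cplx <- spectrum$complex[idx]
  x <- (spectrum$ppm[idx] - spectrum$acq$carrier_ppm) /
    spectrum$acq$spectral_width
  function(p) {
    re <- Re(cplx * exp(1i * (p[1] + p[2] * x) * pi / 180))
    sum(pmin(re, 0)^2)
  }
}

#' Automatic phase correction
#'
#' Chooses zeroth- and first-order phases minimising the sum of squared
#' negative absorption intensities, a simple and robust objective for spectra
#' whose true absorption peaks are non-negative.  An already-phased spectrum is
#' a fixed point (phases within a degree of zero).
#'
#' The phases are estimated from the peaks themselves.  Peaks are located on
#' the magnitude spectrum (magnitude is phase-invariant): either inside the
#' caller's declared `windows`, or --- when none are given --- by iterative
#' peak-picking (take the strongest remaining point, claim its half-height
#' cluster, mask its neighbourhood, repeat).  For each peak the phase that
#' renders it absorptive is read off directly as minus the argument of the
#' complex signal summed over the cluster at half height and above: the
#' dispersive component cancels by antisymmetry around the peak, and the
#' half-height core is insensitive to the tails of distant intense lines.  An
#' amplitude-weighted linear fit of those per-peak phases against position
#' yields (phi0, phi1); a single usable peak determines phi0 only.  With
#' several peaks the 360-degree ambiguity between them is resolved by scoring
#' each candidate wrap against a negativity objective (the sum of squared
#' negative absorption intensities over the highest-magnitude points plus a
#' uniform baseline subsample).  The per-peak phase readout is noise-robust
#' (its error scales inversely with the peak's summed amplitude), so no
#' further noise-sensitive optimisation is applied.
#'
#' The first-order phase is restricted to `phi1_limit` degrees across the
#' spectral width: larger ramps make the problem degenerate (adding a full
#' turn between two narrow peaks leaves both positive) and do not occur in
#' well-digitised 1D data.
#'
#' Pure-noise input completes without error: the phases stay at zero and the
#' processing record is flagged `low_signal`.
#'
#' @param spectrum An `nmr_spectrum` retaining its complex data.
#' @param windows Optional list of declared [peak_window()]s in which to read
#'   peak phases; windows without a detectable peak are skipped.
#' @param search `"global"` or `"local"`; `"local"` assumes the spectrum is
#'   already near absorption mode and skips the wrap-ambiguity scan.
#' @param max_eval_points Maximum number of points used by the wrap-scoring
#'   objective.
#' @param phi1_limit Bound on the first-order phase in degrees.
#' @return The phased spectrum; the applied `(phi0, phi1)` are recorded in the
#'   processing record under step `"auto_phase"`.
#' @export
auto_phase <- function(spectrum, windows = NULL,
                       search = c("global", "local"),
                       max_eval_points = 8192, phi1_limit = 200) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  search <- match.arg(search)
  m <- length(spectrum$complex)
  cplx <- spectrum$complex
  mag <- Mod(cplx)
  noise_floor <- stats::median(mag) / 1.1774  # Rayleigh median -> sigma
  low_signal <- max(mag) < 8 * noise_floor

  # half-height cluster around a local maximum
  half_cluster <- function(p) {
    h <- mag[p] / 2
    lo <- p
    while (lo > 1L && mag[lo - 1L] >= h) lo <- lo - 1L
    hi <- p
    while (hi < m && mag[hi + 1L] >= h) hi <- hi + 1L
    lo:hi
  }

  clusters <- list()
  if (!low_signal) {
    if (!is.null(windows)) {
      if (inherits(windows, "peak_window")) windows <- list(windows)
      for (w in windows) {
        iw <- window_index(spectrum, w, partial = TRUE)
        if (!length(iw)) next
        p <- iw[which.max(mag[iw])]
        if (mag[p] < 8 * noise_floor) next   # no detectable peak here
        clusters[[length(clusters) + 1L]] <- half_cluster(p)
      }
    } else {
      remaining <- mag
      first_max <- max(mag)
      for (k in seq_len(8L)) {
        p <- which.max(remaining)
        if (remaining[p] < max(8 * noise_floor, 5e-3 * first_max)) break
        # walk the half-height cluster on the masked copy so an earlier peak's
        # territory is never re-entered
        h <- remaining[p] / 2
        lo <- p
        while (lo > 1L && remaining[lo - 1L] >= h) lo <- lo - 1L
        hi <- p
        while (hi < m && remaining[hi + 1L] >= h) hi <- hi + 1L
        cl <- lo:hi
        halfw <- max(length(cl) %/% 2L, 2L)
        mask <- max(1L, p - 20L * halfw):min(m, p + 20L * halfw)
        remaining[mask] <- 0
        # a genuine peak falls to half height on both sides; a fragment of a
        # stronger line's tail (cut by an earlier mask) does not
        if (mag[lo] > 0.75 * mag[p] || mag[hi] > 0.75 * mag[p]) next
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
    if (!length(clusters)) low_signal <- TRUE
  }

  if (m > max_eval_points) {
    k <- max_eval_points %/% 2
    mag_idx <- order(mag, decreasing = TRUE)[seq_len(k)]
    idx <- sort(unique(c(mag_idx, round(seq(1, m, length.out = k)))))
  } else {
    idx <- seq_len(m)
  }
  obj <- phase_objective(spectrum, idx)

  phi0 <- 0
  phi1 <- 0
  if (!low_signal) {
    x <- (spectrum$ppm - spectrum$acq$carrier_ppm) / spectrum$acq$spectral_width
    xc <- vapply(clusters, function(i) x[i[which.max(mag[i])]], numeric(1))
    wc <- vapply(clusters, function(i) sum(mag[i])^2, numeric(1))
    # phase readout per cluster, after removing the locally linear complex
    # trend fitted on flanking margins -- this cancels the smooth tails that
    # distant intense lines lay underneath a weak peak, which would otherwise
    # bias the argument
    cluster_phase <- function(cl) {
      # Weighted sum over a window around the apex.  The locally linear
      # complex trend fitted on flanking margins is removed first (it carries
      # the smooth tails that distant intense lines lay underneath a weak
      # peak).  The dispersive component of the peak's own lineshape is odd
      # about the line centre, so it cancels under weights that are even about
      # the centre: triangular weights centred on the sub-grid apex (parabolic
      # interpolation of the detrended magnitude) achieve that to second
      # order even though the apex falls between grid points.
      p <- cl[which.max(mag[cl])]
      L <- max(length(cl), 3L)
      k <- min(2L * L, p - 1L, m - p)
      win <- (p - k):(p + k)
      fl <- c(seq.int(max(1L, p - 3L * k), p - k - 1L),
              seq.int(p + k + 1L, min(m, p + 3L * k)))
      fl <- fl[fl >= 1L & fl <= m]
      z <- cplx[win]
      if (length(fl) >= 8) {
        fr <- stats::lm.fit(cbind(1, fl), Re(cplx[fl]))$coefficients
        fi <- stats::lm.fit(cbind(1, fl), Im(cplx[fl]))$coefficients
        z <- z - complex(real = fr[1] + fr[2] * win,
                         imaginary = fi[1] + fi[2] * win)
      }
      mz <- Mod(z)
      pm <- which.max(mz)
      ctr <- pm
      if (pm > 1 && pm < length(mz)) {
        den <- mz[pm - 1] - 2 * mz[pm] + mz[pm + 1]
        if (den < 0) ctr <- pm + 0.5 * (mz[pm - 1] - mz[pm + 1]) / den
      }
      w <- pmax(0, 1 - abs(seq_along(z) - ctr) / k)
      -Arg(sum(w * z)) * 180 / pi
    }
    target <- vapply(clusters, cluster_phase, numeric(1))
    if (length(clusters) == 1) {
      phi0 <- target[1]
    } else {
      ref <- which.max(wc)
      others <- setdiff(seq_along(clusters), ref)
      wraps <- if (search == "global" && length(others) <= 4) {
        as.matrix(expand.grid(rep(list(c(-1, 0, 1)), length(others))))
      } else {
        matrix(0, nrow = 1, ncol = length(others))
      }
      best <- Inf
      for (r in seq_len(nrow(wraps))) {
        tgt <- target
        tgt[others] <- tgt[others] + 360 * wraps[r, ]
        fit <- stats::lm.wfit(cbind(1, xc), tgt, w = wc)
        cand <- unname(fit$coefficients)
        if (anyNA(cand) || abs(cand[2]) > phi1_limit) next
        val <- obj(cand)
        if (val < best) {
          best <- val
          phi0 <- cand[1]
          phi1 <- cand[2]
        }
      }
    }
  }
  phi0 <- ((phi0 + 180) %% 360) - 180
  out <- apply_phase(spectrum, phi0, phi1)
  # rewrite the record entry so replay identifies the automatic step
  out$record[[length(out$record)]] <- list(step = "auto_phase", phi0 = phi0,
                                           phi1 = phi1,
                                           low_signal = low_signal)
  out
}

#' Polynomial baseline correction
#'
#' Fits a polynomial of order `poly_order` to the absorption intensity at
#' points lying outside every exclusion window (the declared peaks) and
#' subtracts the fitted baseline from the whole spectrum.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param exclude_windows List of [peak_window()]s to exclude from the fit.
#' @param poly_order Polynomial order, 0 to 3.
#' @return The corrected spectrum.
#' @export
baseline_correct <- function(spectrum, exclude_windows = list(),
                             poly_order = 1) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (!poly_order %in% 0:3) {
    stop("`poly_order` must be in 0..3", call. = FALSE)
  }
  if (inherits(exclude_windows, "peak_window")) {
    exclude_windows <- list(exclude_windows)
  }
  m <- length(spectrum$intensity)
  keep <- rep(TRUE, m)
  for (w in exclude_windows) keep[window_index(spectrum, w, partial = TRUE)] <- FALSE
  if (sum(!keep) > 0.8 * m) {
    stop("exclusion windows cover more than 80% of the axis", call. = FALSE)
  }
  x <- (spectrum$ppm - spectrum$acq$carrier_ppm) / spectrum$acq$spectral_width
  if (poly_order == 0) {
    base <- rep(mean(spectrum$intensity[keep]), m)
    coefs <- mean(spectrum$intensity[keep])
  } else {
    X <- outer(x, 0:poly_order, `^`)
    fit <- stats::lm.fit(X[keep, , drop = FALSE], spectrum$intensity[keep])
    coefs <- fit$coefficients
    base <- drop(X %*% coefs)
  }
  spectrum$complex <- spectrum$complex - base
  spectrum$intensity <- spectrum$intensity - base
  spectrum$record <- c(spectrum$record,
                       list(list(step = "baseline_correct",
                                 poly_order = poly_order,
                                 exclude_windows = exclude_windows,
                                 coefficients = unname(coefs))))
  spectrum
}

#' Calibrate the ppm axis against the internal reference peak
#'
#' Locates the reference peak (maximum absorption intensity inside
#' `reference_window`), verifies it is detectable (SNR >= 3 against
#' `noise_region` when one is given), and shifts the axis so the reference
#' lands exactly at `reference_true` ppm.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param reference_true True shift of the reference in ppm (TFA: -76).
#' @param reference_window Window in which to search for the reference peak.
#' @param noise_region Optional signal-free [peak_window()] used for the SNR
#'   check.
#' @param observed Optional observed reference position in ppm; when given the
#'   search and SNR check are skipped.
#' @return The spectrum with a shifted ppm axis.
#' @export
calibrate_ppm <- function(spectrum, reference_true = -76,
                          reference_window = peak_window(reference_true, 1.5),
                          noise_region = NULL, observed = NULL) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (is.null(observed)) {
    idx <- window_index(spectrum, reference_window)
    if (!is.null(noise_region)) {
      snr <- compute_snr(spectrum, reference_window, noise_region)
      if (snr < 3) {
        stop(sprintf("reference peak not found (SNR %.2f < 3 in the reference window)",
                     snr), call. = FALSE)
      }
    }
    observed <- spectrum$ppm[idx[which.max(spectrum$intensity[idx])]]
  }
  shift <- reference_true - observed
  if (abs(shift) > 10) {
    stop(sprintf("calibration shift of %.2f ppm exceeds 10 ppm; probable peak mis-identification",
                 shift), call. = FALSE)
  }
  spectrum$ppm <- spectrum$ppm + shift
  spectrum$record <- c(spectrum$record,
                       list(list(step = "calibrate_ppm", shift = shift,
                                 observed = observed,
                                 reference_true = reference_true)))
  spectrum
}

#' Windowed peak integral with a noise-propagated standard error
#'
#' Integrates the absorption intensity over `window` by the trapezoidal rule
#' and attaches a standard error derived from the baseline noise over the same
#' interval width: `noise_se = RMS(noise region) * axis_step *
#' sqrt(n_points_in_window * zero_fill_factor)`.  The `zero_fill_factor`
#' corrects for the correlation that zero-filling introduces between adjacent
#' spectrum points (zero-filling interpolates; it does not add information).
#'
#' When `local_baseline = TRUE`, a straight line fitted to the flanking
#' margins (from one to `1 + flank` half-widths on either side of the window)
#' is subtracted inside the window first.  This is the integral bias/slope
#' correction of standard quantitative NMR practice: it removes the locally
#' smooth tails that distant intense resonances (and their residual dispersive
#' components under imperfect phasing) spread across the window, which a
#' global polynomial baseline cannot follow.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window [peak_window()] over the peak.
#' @param noise_region [peak_window()] over a signal-free region, disjoint from
#'   `window`.
#' @param local_baseline Subtract a linear fit of the flanking margins.
#' @param flank Width of each flanking margin in units of the window
#'   half-width.
#' @return An object of class `integral_result` with fields `value`,
#'   `noise_se` and `n_points`.
#' @export
integrate_peak <- function(spectrum, window, noise_region,
                           local_baseline = FALSE, flank = 2) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(window, "peak_window"),
            inherits(noise_region, "peak_window"))
  if (abs(window$center - noise_region$center) <
      window$half_width + noise_region$half_width) {
    stop("`window` and `noise_region` must be disjoint", call. = FALSE)
  }
  idx <- window_index(spectrum, window)
  nidx <- window_index(spectrum, noise_region)
  n <- length(idx)
  ord <- idx[order(spectrum$ppm[idx])]      # integrate over increasing ppm
  x <- spectrum$ppm[ord]
  y <- spectrum$intensity[ord]
  # extend to the exact window boundaries by linear interpolation, so the
  # captured fraction does not jump with the grid alignment of the edges
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  xs <- rev(spectrum$ppm)
  ys <- rev(spectrum$intensity)
  edge <- stats::approx(xs, ys, xout = c(lo, hi), rule = 2)$y
  x <- c(lo, x, hi)
  y <- c(edge[1], y, edge[2])
  detrended <- FALSE
  n_flank <- 0L
  if (local_baseline) {
    fit <- flank_line(spectrum, window, flank)
    if (!is.null(fit)) {
      y <- y - (fit$coef[1] + fit$coef[2] * x)
      detrended <- TRUE
      n_flank <- fit$n
    }
  }
  m_all <- length(x)
  value <- sum(diff(x) * (y[-1] + y[-m_all]) / 2)
  noise <- spectrum$intensity[nidx]
  rms <- sqrt(mean(noise^2))
  step <- abs(stats::median(diff(spectrum$ppm)))
  # Zero-filling interpolates: the window-sum variance of zero-filled noise is
  # that of n/z independent points times z^2/2 (the padded DFT keeps only the
  # positive-time half of the window kernel), so the effective count is n*z/2
  # for z >= 2 and n for z = 1.
  z <- spectrum$zero_fill_factor
  n_eff <- if (z == 1) n else n * z / 2
  noise_se <- rms * step * sqrt(n_eff)
  # subtracting the flank-fitted line propagates the flanks' noise into the
  # window sum; with symmetric flanks the variance inflates by 1 + n/n_flank
  if (detrended) noise_se <- noise_se * sqrt(1 + n / n_flank)
  structure(list(value = value, noise_se = noise_se, n_points = n),
            class = "integral_result")
}

#' @export
print.integral_result <- function(x, ...) {
  cat(sprintf("<integral_result> value %.6g +/- %.3g (%d points)\n",
              x$value, x$noise_se, x$n_points))
  invisible(x)
}

#' Signal-to-noise ratio of a peak
#'
#' SNR = (maximum absorption intensity inside `peak_window`) / (RMS of the
#' absorption intensity over `noise_region`).  No vendor factor of 2 is
#' applied (some vendor software divides by twice the noise); thresholds such
#' as the LOD's SNR = 2 are configuration constants so either convention can be
#' reproduced.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param peak_window [peak_window()] over the peak.
#' @param noise_region Signal-free [peak_window()].
#' @return A single dimensionless SNR value.
#' @export
compute_snr <- function(spectrum, peak_window, noise_region) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  idx <- window_index(spectrum, peak_window)
  nidx <- window_index(spectrum, noise_region)
  rms <- sqrt(mean(spectrum$intensity[nidx]^2))
  if (rms == 0) {
    stop("noiseless spectrum; SNR undefined", call. = FALSE)
  }
  max(spectrum$intensity[idx]) / rms
}

#' Replay a recorded processing pipeline on an FID
#'
#' Re-applies every step stored in a spectrum's processing record (transform
#' parameters, recorded phases, baseline coefficients' refit, axis shift) to a
#' raw FID.  Replaying the record of a spectrum on the FID that produced it
#' reproduces the spectrum bit-identically; recorded phases are re-applied
#' directly rather than re-optimised.
#'
#' @param fid The raw [new_fid()].
#' @param record A processing record (`spectrum$record`).
#' @return An `nmr_spectrum`.
#' @export
replay_processing <- function(fid, record) {
  spectrum <- NULL
  for (s in record) {
    spectrum <- switch(
      s$step,
      fid_to_spectrum = fid_to_spectrum(fid, s$zero_fill_factor,
                                        s$apodization_lb),
      apply_phase = apply_phase(spectrum, s$phi0, s$phi1),
      auto_phase = {
        out <- apply_phase(spectrum, s$phi0, s$phi1)
        out$record[[length(out$record)]] <- s
        out
      },
      baseline_correct = baseline_correct(spectrum, s$exclude_windows,
                                          s$poly_order),
      calibrate_ppm = calibrate_ppm(spectrum, s$reference_true,
                                    observed = s$observed),
      stop(sprintf("unknown processing step '%s'", s$step), call. = FALSE)
    )
  }
  spectrum
}
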