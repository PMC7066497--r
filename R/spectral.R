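#' Spectral-analysis settings
#'
#' Controls how trajectories are reduced to power spectra and summary
#' measures.  The defaults analyse the final \code{analysis_window}
#' fraction of the trajectory (the first part is discarded as transient)
#' with Welch's method: mean removal, Hann-windowed segments, and
#' zero-padding of the FFT to at least the target frequency
#' \code{resolution}.  With the default single segment the estimator is a
#' zero-padded Hann periodogram, which resolves slow (tremor-band) rhythms
#' that multi-segment averaging over short records cannot.
#'
#' @param analysis_window fraction of the trajectory analysed, taken from
#'   the end (default 0.5: the second half).
#' @param n_segments number of Welch segments (default 1).
#' @param overlap fractional overlap between segments when
#'   \code{n_segments > 1} (default 0.5).
#' @param resolution target frequency-grid resolution (Hz); the FFT is
#'   zero-padded to the next power of two reaching it.
#' @param min_freq lowest frequency (Hz) considered when locating spectral
#'   peaks; excludes the DC-adjacent leakage of the window.
#' @param peak_floor_factor a spectral peak counts as genuine oscillation
#'   only if it exceeds this multiple of the median in-band power.
#' @param subharmonic_ratio strongly non-sinusoidal limit cycles can carry
#'   more power in a harmonic than at the cycle rate itself;
#'   \code{\link{dominant_frequency}} therefore steps down from the maximal
#'   peak to a sub-harmonic when a local peak at the candidate fundamental
#'   holds at least this fraction of the maximal peak's power.
#' @return An object of class \code{spectral_settings}.
#' @export
spectral_settings <- function(analysis_window = 0.5, n_segments = 1,
                              overlap = 0.5, resolution = 0.25,
                              min_freq = 0.5, peak_floor_factor = 10,
                              subharmonic_ratio = 0.25) {
  if (analysis_window <= 0 || analysis_window > 1)
    stop("'analysis_window' must be in (0, 1]", call. = FALSE)
  if (resolution <= 0) stop("'resolution' must be positive", call. = FALSE)
  if (n_segments < 1) stop("'n_segments' must be >= 1", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("'overlap' must be in [0, 1)", call. = FALSE)
  structure(list(analysis_window = analysis_window, n_segments = n_segments,
                 overlap = overlap, resolution = resolution,
                 min_freq = min_freq, peak_floor_factor = peak_floor_factor,
                 subharmonic_ratio = subharmonic_ratio),
            class = "spectral_settings")
}

# Index range of the analysis window (final fraction of the record).
.analysis_idx <- function(n, settings) {
  start <- n - floor(n * settings$analysis_window) + 1L
  max(1L, start):n
}

#' Welch power spectral density
#'
#' One-sided Welch PSD of a uniformly sampled signal: the mean is removed,
#' the signal is split into \code{n_segments} Hann-windowed segments with
#' the configured overlap, each segment is zero-padded to a power of two
#' giving at least the target frequency resolution, and the squared
#' spectra are averaged.
#'
#' @param signal numeric vector (>= 64 samples).
#' @param fs sampling frequency (Hz).
#' @param settings a \code{\link{spectral_settings}} object.
#' @return An object of class \code{wc_psd}: list with \code{freq} (Hz,
#'   from 0 to \code{fs/2}), \code{power} (non-negative), \code{fs},
#'   \code{resolution} (achieved grid spacing) and \code{settings}.
#' @export
power_spectrum <- function(signal, fs, settings = spectral_settings()) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 64L)
    stop("signal too short for spectral analysis (need >= 64 samples)",
         call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("'fs' must be a positive sampling frequency", call. = FALSE)
  x <- signal - mean(signal)

  ns <- settings$n_segments
  step <- 1 - settings$overlap
  seg_len <- if (ns == 1L) n else floor(n / (1 + (ns - 1) * step))
  if (seg_len < 64L)
    stop("segments too short; reduce 'n_segments'", call. = FALSE)
  starts <- if (ns == 1L) 1L else
    round(seq(1L, n - seg_len + 1L, length.out = ns))

  nfft <- 2^ceiling(log2(max(seg_len, fs / settings$resolution)))
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))  # Hann
  u <- sum(win^2)

  acc <- numeric(nfft %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    sp <- fft(c(seg, numeric(nfft - seg_len)))
    acc <- acc + Mod(sp[seq_len(nfft %/% 2 + 1L)])^2
  }
  pw <- acc / (length(starts) * fs * u)
  pw[c(-1, -length(pw))] <- 2 * pw[c(-1, -length(pw))]  # one-sided
  freq <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft

  structure(list(freq = freq, power = pw, fs = fs,
                 resolution = fs / nfft, settings = settings),
            class = "wc_psd")
}

#' Dominant spectral frequency
#'
#' Frequency of the maximal PSD peak at or above \code{min_freq}, corrected
#' to the fundamental of its harmonic comb, or \code{NA} when no peak
#' stands out of the spectrum (the maximal peak must exceed
#' \code{peak_floor_factor} times the median in-band power, and a tiny
#' absolute floor guards numerically silent signals).
#'
#' Relaxation-type limit cycles produce spectra in which a harmonic of the
#' cycle rate can marginally out-power the fundamental (the slow tremor
#' rhythm of this network is such a case).  When a local peak at
#' \code{f_max / n} (n = 2..6) carries at least
#' \code{subharmonic_ratio} of the maximal peak's power, the lowest such
#' sub-harmonic is reported as the dominant frequency; a pure tone or a
#' mildly distorted cycle is unaffected.
#'
#' @param psd a \code{\link{power_spectrum}} result.
#' @param min_freq lowest admissible frequency (Hz); defaults to the value
#'   in the PSD's settings.
#' @return Dominant frequency (Hz, on the PSD grid) or \code{NA_real_}.
#' @export
dominant_frequency <- function(psd, min_freq = NULL) {
  stopifnot(inherits(psd, "wc_psd"))
  if (is.null(min_freq)) min_freq <- psd$settings$min_freq
  band <- which(psd$freq >= min_freq)
  if (!length(band)) return(NA_real_)
  p <- psd$power[band]
  pk <- max(p)
  if (pk <= 1e-16 || pk < psd$settings$peak_floor_factor * median(p))
    return(NA_real_)
  imax <- band[which.max(p)]
  fmax <- psd$freq[imax]

  # local maxima of the in-band spectrum (comb teeth)
  pw <- psd$power
  loc <- band[-c(1, length(band))]
  is_pk <- pw[loc] > pw[loc - 1L] & pw[loc] >= pw[loc + 1L]
  pk_idx <- loc[is_pk]
  ratio <- psd$settings$subharmonic_ratio

  best <- fmax
  for (n in 2:6) {
    fc <- fmax / n
    if (fc < min_freq) break
    near <- pk_idx[abs(psd$freq[pk_idx] - fc) <= 1.5 * psd$resolution]
    if (length(near) && max(pw[near]) >= ratio * pw[imax])
      best <- psd$freq[near[which.max(pw[near])]]
  }
  best
}

#' Per-population oscillation amplitude
#'
#' Peak-to-trough amplitude (max minus min of the active fraction) of each
#' population over the analysis window.
#'
#' @param traj a \code{wc_trajectory}.
#' @param settings a \code{\link{spectral_settings}} object (only the
#'   analysis window is used).
#' @return Named numeric vector of length 7 (activity units, >= 0).
#' @export
oscillation_amplitude <- function(traj, settings = spectral_settings()) {
  stopifnot(inherits(traj, "wc_trajectory"))
  idx <- .analysis_idx(nrow(traj$activity), settings)
  a <- traj$activity[idx, , drop = FALSE]
  apply(a, 2, max) - apply(a, 2, min)
}

#' Oscillation test
#'
#' A trajectory counts as oscillatory when (a) some non-DCN population has
#' peak-to-trough amplitude above \code{epsilon} in the analysis window,
#' and (b) the spectrum of the largest-amplitude non-DCN population has a
#' peak above \code{min_freq} that clears the median-power floor by
#' \code{peak_floor_factor}.  The two-part test rejects both fixed points
#' (condition a) and slow aperiodic drift (condition b).
#'
#' @param traj a \code{wc_trajectory}.
#' @param settings a \code{\link{spectral_settings}} object.
#' @param epsilon amplitude threshold (activity units, default 1e-3).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_oscillatory <- function(traj, settings = spectral_settings(),
                           epsilon = 1e-3) {
  amp <- oscillation_amplitude(traj, settings)
  amp_nd <- amp[setdiff(POPULATIONS, "DCN")]
  if (max(amp_nd) <= epsilon) return(FALSE)
  ref <- names(which.max(amp_nd))
  idx <- .analysis_idx(nrow(traj$activity), settings)
  psd <- power_spectrum(traj$activity[idx, ref], 1 / traj$config$dt_output,
                        settings)
  !is.na(dominant_frequency(psd))
}

#' Spectral summary of a trajectory
#'
#' Reduces a trajectory to the quantities the experiment battery records:
#' per-population Welch PSDs, the dominant network frequency, per-population
#' peak-to-trough amplitudes, and the oscillation flag.
#'
#' The dominant frequency is read from the PSD of the \code{reference}
#' population; by default this is the largest-amplitude non-DCN population,
#' which is robust when individual populations sit near a fixed point.  In
#' oscillatory regimes all non-DCN populations share one frequency, so the
#' choice is immaterial there.
#'
#' @param traj a \code{wc_trajectory}.
#' @param settings a \code{\link{spectral_settings}} object.
#' @param reference population whose PSD defines the dominant frequency,
#'   or \code{NULL} for the largest-amplitude non-DCN population.
#' @param epsilon amplitude threshold passed to \code{\link{is_oscillatory}}.
#' @param keep_psd keep the full per-population PSDs (set \code{FALSE} in
#'   large sweeps to save memory; the reference PSD is always kept).
#' @return An object of class \code{wc_spectral_summary}.
#' @export
spectral_summary <- function(traj, settings = spectral_settings(),
                             reference = NULL, epsilon = 1e-3,
                             keep_psd = TRUE) {
  stopifnot(inherits(traj, "wc_trajectory"))
  fs <- 1 / traj$config$dt_output
  idx <- .analysis_idx(nrow(traj$activity), settings)
  amp <- oscillation_amplitude(traj, settings)
  amp_nd <- amp[setdiff(POPULATIONS, "DCN")]
  if (is.null(reference)) reference <- names(which.max(amp_nd))
  reference <- match.arg(reference, POPULATIONS)

  psd <- NULL
  if (keep_psd)
    psd <- lapply(setNames(POPULATIONS, POPULATIONS), function(p)
      power_spectrum(traj$activity[idx, p], fs, settings))
  ref_psd <- if (keep_psd) psd[[reference]] else
    power_spectrum(traj$activity[idx, reference], fs, settings)

  osc <- max(amp_nd) > epsilon && !is.na(dominant_frequency(ref_psd))
  dom <- if (osc) dominant_frequency(ref_psd) else NA_real_

  structure(list(dominant_frequency = dom, oscillatory = osc,
                 amplitude = amp, reference = reference,
                 resolution = ref_psd$resolution,
                 psd = psd, ref_psd = ref_psd,
                 dbs = traj$dbs, settings = settings, epsilon = epsilon),
            class = "wc_spectral_summary")
}

#' @export
print.wc_spectral_summary <- function(x, ...) {
  cat("<wc_spectral_summary>\n")
  if (x$oscillatory)
    cat(sprintf("  oscillatory at %.2f Hz (reference %s, grid %.3f Hz)\n",
                x$dominant_frequency, x$reference, x$resolution))
  else
    cat("  non-oscillatory\n")
  amp <- round(x$amplitude, 4)
  cat("  peak-to-trough: ",
      paste(sprintf("%s=%g", names(amp), amp), collapse = " "), "\n",
      sep = "")
  if (!is.null(x$dbs))
    cat(sprintf("  under DBS: %s, %g a.u. at %g Hz\n",
                x$dbs$target, x$dbs$amplitude, x$dbs$frequency))
  invisible(x)
}

#' @rdname spectral_summary
#' @param object a \code{wc_trajectory}.
#' @param ... passed on to \code{spectral_summary}.
#' @export
summary.wc_trajectory <- function(object, ...) {
  spectral_summary(object, ...)
}

#' @export
plot.wc_psd <- function(x, xlim = c(0, 100), log = "y", ...) {
  keep <- x$freq >= 0 & x$freq <= xlim[2]
  pw <- pmax(x$power[keep], 1e-300)
  graphics::plot(x$freq[keep], pw, type = "l", xlim = xlim, log = log,
                 xlab = "frequency (Hz)", ylab = "power (a.u.^2/Hz)", ...)
  invisible(x)
}
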