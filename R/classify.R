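#' Frequency-band table
#'
#' Band edges (Hz) used by \code{\link{classify_state}}: tremor [3, 8),
#' beta [13, 30), gamma [30, 90).  A dominant frequency falling between
#' bands (for example the 12 Hz rhythm reached from the tremor state by
#' strengthening the STN-to-GPe weight) is labelled \code{other_band}.
#'
#' @param tremor,beta,gamma numeric \code{c(lower, upper)} edges; each band
#'   is the half-open interval [lower, upper).
#' @return Named list of band edges.
#' @export
band_table <- function(tremor = c(3, 8), beta = c(13, 30),
                       gamma = c(30, 90)) {
  for (b in list(tremor, beta, gamma))
    if (length(b) != 2L || b[1] >= b[2])
      stop("each band must be c(lower, upper) with lower < upper",
           call. = FALSE)
  list(tremor = tremor, beta = beta, gamma = gamma)
}

#' Suppression test against a no-DBS baseline
#'
#' A stimulated trajectory counts as suppressed when the network
#' oscillation — the largest peak-to-trough amplitude over the populations
#' that are neither the DCN nor the directly stimulated target — has
#' fallen below \code{suppression_fraction} of the same measure in the
#' baseline, and the residual rhythm (if any) is not slower than the
#' baseline rhythm.  The stimulated population is excluded because it
#' tracks the forcing waveform directly whatever the rest of the network
#' does; stimulating the GPe, for instance, silences the GPe itself while
#' the remaining populations keep their tremor rhythm, and that network
#' state is not suppressed.  The fraction is a package convention (the
#' qualitative notion being formalized is "high-amplitude low-frequency
#' activity replaced by low-amplitude high-frequency activity"); threshold
#' results must always be reported together with it.
#'
#' @param summary a \code{\link{spectral_summary}} of the stimulated run
#'   (its \code{dbs} field identifies the stimulated population).
#' @param baseline the \code{spectral_summary} of the no-DBS run with the
#'   same parameters.
#' @param suppression_fraction amplitude ratio below which the oscillation
#'   counts as suppressed (default 0.2).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_suppressed <- function(summary, baseline, suppression_fraction = 0.2) {
  stopifnot(inherits(summary, "wc_spectral_summary"),
            inherits(baseline, "wc_spectral_summary"))
  excl <- "DCN"
  if (!is.null(summary$dbs)) excl <- c(excl, summary$dbs$target)
  rest <- setdiff(POPULATIONS, excl)
  amp <- max(summary$amplitude[rest])
  amp0 <- max(baseline$amplitude[rest])
  if (amp >= suppression_fraction * amp0) return(FALSE)
  # residual rhythm must not be slower than the baseline rhythm
  is.na(summary$dominant_frequency) ||
    is.na(baseline$dominant_frequency) ||
    summary$dominant_frequency > baseline$dominant_frequency
}

#' Classify the dynamical state of the network
#'
#' Maps a spectral summary to one label:
#' \describe{
#'   \item{\code{non_oscillatory}}{the oscillation test failed;}
#'   \item{\code{tremor_band}, \code{beta_band}, \code{gamma_band}}{the
#'     dominant frequency falls in the corresponding band of
#'     \code{\link{band_table}};}
#'   \item{\code{other_band}}{oscillatory, but the frequency falls between
#'     the configured bands;}
#'   \item{\code{low_amp_high_freq}}{(DBS runs only) the baseline
#'     oscillation is suppressed per \code{\link{is_suppressed}};}
#'   \item{\code{entrained}}{(DBS runs only) the dominant frequency locks
#'     to the stimulation frequency within one frequency-resolution bin.}
#' }
#' For DBS runs the precedence is suppression, then entrainment, then the
#' frequency bands, so a fully suppressed state reads
#' \code{low_amp_high_freq} even when its residual ripple tracks the
#' stimulus.  Band labels of a DBS run describe the surviving network
#' rhythm (e.g. GPe stimulation that leaves the rest of the network in the
#' tremor band).
#'
#' @param summary a \code{\link{spectral_summary}}.
#' @param baseline the no-DBS \code{spectral_summary} at the same
#'   parameters; required when \code{summary} carries a DBS spec.
#' @param bands a \code{\link{band_table}}.
#' @param suppression_fraction passed to \code{\link{is_suppressed}}.
#' @return A single character label.
#' @export
classify_state <- function(summary, baseline = NULL, bands = band_table(),
                           suppression_fraction = 0.2) {
  stopifnot(inherits(summary, "wc_spectral_summary"))
  has_dbs <- !is.null(summary$dbs) && summary$dbs$amplitude > 0
  if (has_dbs && is.null(baseline))
    stop("classifying a DBS run requires the no-DBS 'baseline' summary",
         call. = FALSE)

  if (has_dbs) {
    if (is_suppressed(summary, baseline, suppression_fraction))
      return("low_amp_high_freq")
    if (!summary$oscillatory) return("non_oscillatory")
    if (abs(summary$dominant_frequency - summary$dbs$frequency) <=
        summary$resolution)
      return("entrained")
  } else if (!summary$oscillatory) {
    return("non_oscillatory")
  }

  f <- summary$dominant_frequency
  if (is.na(f)) return("non_oscillatory")
  if (f >= bands$tremor[1] && f < bands$tremor[2]) return("tremor_band")
  if (f >= bands$beta[1] && f < bands$beta[2]) return("beta_band")
  if (f >= bands$gamma[1] && f < bands$gamma[2]) return("gamma_band")
  "other_band"
}

# Peak times (local maxima) of one sampled series, restricted to the
# analysis window.  No sub-sample refinement: at 0.1 ms sampling the grid
# error is far below a cycle.
.peak_times <- function(times, x) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  core <- x[2:(n - 1L)]
  pk <- which(core > x[1:(n - 2L)] & core >= x[3:n]) + 1L
  times[pk]
}

#' Phase ordering of the oscillating populations
#'
#' Ranks the oscillating populations by how soon after the thalamic peak
#' each population peaks within a cycle.  For every thalamic peak the
#' delay to the next peak of each population is taken modulo the dominant
#' period; delays are averaged circularly, and populations are ranked by
#' mean delay in [0, T).  The thalamus therefore ranks first whenever it
#' leads the cycle.  The DCN (a fixed point) and any population with
#' amplitude below \code{epsilon} are excluded.  Ties closer than the
#' sampling step are broken by the cross-correlation lag at zero offset.
#'
#' @param traj an oscillatory \code{wc_trajectory}.
#' @param settings a \code{\link{spectral_settings}} object.
#' @param epsilon amplitude threshold for a population to participate.
#' @return Character vector of population names, leaders first, with the
#'   mean delays (seconds) as the \code{"delay"} attribute.
#' @export
phase_order <- function(traj, settings = spectral_settings(),
                        epsilon = 1e-3) {
  stopifnot(inherits(traj, "wc_trajectory"))
  summ <- spectral_summary(traj, settings, epsilon = epsilon,
                           keep_psd = FALSE)
  if (!summ$oscillatory)
    stop("phase_order requires an oscillatory trajectory", call. = FALSE)
  period <- 1 / summ$dominant_frequency
  idx <- .analysis_idx(nrow(traj$activity), settings)
  tt <- traj$times[idx]

  cand <- setdiff(POPULATIONS, "DCN")
  cand <- cand[summ$amplitude[cand] > epsilon]
  ref <- if ("Th" %in% cand) "Th" else
    names(which.max(summ$amplitude[cand]))

  ref_peaks <- .peak_times(tt, traj$activity[idx, ref])
  if (length(ref_peaks) < 2L)
    stop("too few cycles in the analysis window for phase ordering",
         call. = FALSE)

  delay <- vapply(cand, function(p) {
    pks <- .peak_times(tt, traj$activity[idx, p])
    if (length(pks) == 0L) return(NA_real_)
    # offset to the nearest peak (so the finite-resolution period
    # estimate cannot accumulate across distant cycles), wrapped to [0, T)
    d <- vapply(ref_peaks, function(tr) {
      (pks[which.min(abs(pks - tr))] - tr) %% period
    }, numeric(1))
    ang <- 2 * pi * d / period
    (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * period / (2 * pi)
  }, numeric(1))
  delay <- delay[!is.na(delay)]

  ord <- order(delay)
  # tie-break within one sampling step by cross-correlation lag
  dt <- traj$config$dt_output
  for (i in seq_len(length(ord) - 1L)) {
    a <- ord[i]; b <- ord[i + 1L]
    if (abs(delay[a] - delay[b]) < dt) {
      lag <- .xcorr_lag(traj$activity[idx, names(delay)[a]],
                        traj$activity[idx, names(delay)[b]],
                        max_lag = round(period / (2 * dt)))
      if (lag < 0) { ord[i] <- b; ord[i + 1L] <- a }
    }
  }
  out <- names(delay)[ord]
  attr(out, "delay") <- delay[ord]
  out
}

# Lag (in samples) at which the cross-correlation of a and b is maximal;
# positive means a leads b.
.xcorr_lag <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(a[seq_len(length(a) - l)] * b[(1 + l):length(b)])
    else sum(a[(1 - l):length(a)] * b[seq_len(length(b) + l)])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Per-cycle oscillation amplitudes
#'
#' Splits the analysis window of one population's trace at successive
#' troughs (local minima) and returns the peak-to-trough amplitude of each
#' cycle.  Used to detect burst-like activity, where the cycle amplitudes
#' separate into large (intra-burst) and small (inter-burst) groups.
#'
#' @param traj a \code{wc_trajectory}.
#' @param population population name (default the largest-amplitude
#'   non-DCN population).
#' @param settings a \code{\link{spectral_settings}} object.
#' @return Numeric vector of per-cycle amplitudes (possibly empty).
#' @export
cycle_amplitudes <- function(traj, population = NULL,
                             settings = spectral_settings()) {
  stopifnot(inherits(traj, "wc_trajectory"))
  idx <- .analysis_idx(nrow(traj$activity), settings)
  if (is.null(population)) {
    amp <- oscillation_amplitude(traj, settings)
    population <- names(which.max(amp[setdiff(POPULATIONS, "DCN")]))
  }
  x <- traj$activity[idx, population]
  troughs <- which(diff(sign(diff(x))) > 0) + 1L
  if (length(troughs) < 2L) return(numeric(0))
  vapply(seq_len(length(troughs) - 1L), function(i) {
    seg <- x[troughs[i]:troughs[i + 1L]]
    max(seg) - min(seg)
  }, numeric(1))
}

#' Burst-structure test
#'
#' Detects burst-like (waxing-and-waning) activity from the distribution
#' of per-cycle amplitudes: bursting separates cycles into high-amplitude
#' (intra-burst) and low-amplitude (inter-burst) groups, making the
#' distribution multimodal.  Multimodality is scored with Sarle's
#' bimodality coefficient \eqn{(g_1^2 + 1)/(g_2 + 3(n-1)^2/((n-2)(n-3)))},
#' which exceeds 5/9 for bimodal distributions; near-constant cycle
#' amplitudes (relative spread below \code{min_spread}) are never counted
#' as bursting.
#'
#' @param traj a \code{wc_trajectory}.
#' @param population population to test, or \code{NULL} to test every
#'   non-DCN population and report whether any shows burst structure
#'   (bursting induced by periodic forcing is often concentrated in the
#'   stimulated population).
#' @param settings passed to \code{\link{cycle_amplitudes}}.
#' @param min_spread minimum coefficient of variation of the cycle
#'   amplitudes for bursting to be considered.
#' @return \code{TRUE} or \code{FALSE}, with the per-population
#'   coefficient(s) in the \code{"bimodality"} attribute.
#' @export
is_bursting <- function(traj, population = NULL,
                        settings = spectral_settings(), min_spread = 0.1) {
  pops <- if (is.null(population)) setdiff(POPULATIONS, "DCN") else
    match.arg(population, POPULATIONS)
  bc <- vapply(pops, function(p) {
    ca <- cycle_amplitudes(traj, p, settings)
    n <- length(ca)
    if (n < 4L || mean(ca) == 0) return(NA_real_)
    if (sd(ca) / mean(ca) < min_spread) return(NA_real_)
    m <- mean(ca); s <- sd(ca)
    g1 <- mean((ca - m)^3) / s^3
    g2 <- mean((ca - m)^4) / s^4 - 3
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }, numeric(1))
  structure(any(!is.na(bc) & bc > 5 / 9), bimodality = bc)
}
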