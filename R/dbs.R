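#' DBS stimulus specification
#'
#' Describes a deep-brain-stimulation input: a square wave of peak
#' amplitude \code{A} (a.u.) at frequency \code{f} (Hz), delivered into the
#' sigmoid argument of one target population.  The waveform is the
#' truncated odd-harmonic Fourier series
#' \deqn{\mathrm{DBS}(t) = A\,\frac{4}{\pi} \sum_{n=1,3,\dots}^{n_{max}}
#'       \frac{1}{n}\,\sin(2\pi n f t),}
#' which converges to a \eqn{\pm A} square wave as \eqn{n_{max}\to\infty};
#' the default truncation at \eqn{n_{max} = 1001} keeps the Gibbs ripple of
#' the stimulus as an explicit, reproducible feature.  An ideal (exact)
#' square wave is available via \code{waveform = "ideal"} for sensitivity
#' checks.
#'
#' @param target stimulated population: \code{"STN"}, \code{"Th"},
#'   \code{"GPi"} or \code{"GPe"} (the four clinical targets).
#' @param amplitude peak amplitude \code{A} (a.u., non-negative).
#' @param frequency stimulation frequency (Hz, positive).
#' @param n_max highest odd harmonic retained in the series (odd, >= 1).
#' @param onset time (seconds) at which stimulation switches on; the
#'   waveform is 0 before \code{onset}.
#' @param waveform \code{"series"} (truncated Fourier series, default) or
#'   \code{"ideal"} (exact square wave).
#' @return An object of class \code{dbs_spec}.
#' @examples
#' spec <- dbs_spec("STN", amplitude = 5, frequency = 120)
#' dbs_waveform(1 / (4 * 120), spec)  # plateau midpoint, ~ +5
#' @export
dbs_spec <- function(target = c("STN", "Th", "GPi", "GPe"),
                     amplitude, frequency, n_max = 1001, onset = 0,
                     waveform = c("series", "ideal")) {
  target <- match.arg(target)
  waveform <- match.arg(waveform)
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude < 0)
    stop("'amplitude' must be a single finite non-negative number",
         call. = FALSE)
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0)
    stop("'frequency' must be a single positive number (Hz)", call. = FALSE)
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L || n_max %% 2L == 0L)
    stop("'n_max' must be an odd integer >= 1", call. = FALSE)
  if (!is.numeric(onset) || length(onset) != 1L || !is.finite(onset) ||
      onset < 0)
    stop("'onset' must be a single non-negative time (seconds)",
         call. = FALSE)
  structure(list(target = target, amplitude = amplitude,
                 frequency = frequency, n_max = n_max, onset = onset,
                 waveform = waveform),
            class = "dbs_spec")
}

#' Evaluate the DBS forcing waveform
#'
#' Direct (vectorized) evaluation of the stimulus time course described by
#' a \code{\link{dbs_spec}}.  The compiled integrator evaluates the same
#' series internally via a harmonic recurrence; this R implementation sums
#' the sine terms explicitly and serves as its independent cross-check.
#'
#' @param t time or times (seconds, >= 0).
#' @param spec a \code{\link{dbs_spec}}.
#' @return Numeric vector of forcing values (a.u.), zero before
#'   \code{spec$onset}.
#' @export
dbs_waveform <- function(t, spec) {
  stopifnot(inherits(spec, "dbs_spec"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite", call. = FALSE)
  out <- numeric(length(t))
  on <- t >= spec$onset
  if (spec$amplitude == 0 || !any(on)) return(out)
  tt <- t[on] - spec$onset
  if (spec$waveform == "ideal") {
    ph <- (tt * spec$frequency) %% 1
    out[on] <- spec$amplitude * ifelse(ph == 0 | ph == 0.5, 0,
                                       ifelse(ph < 0.5, 1, -1))
    return(out)
  }
  n <- seq(1L, spec$n_max, by = 2L)
  # rows: times, cols: harmonics; chunk to bound the temporary matrix
  vals <- numeric(length(tt))
  chunk <- max(1L, floor(5e6 / length(n)))
  for (i0 in seq(1L, length(tt), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(tt))
    m <- sin(outer(2 * pi * spec$frequency * tt[idx], n)) %*% (1 / n)
    vals[idx] <- as.numeric(m)
  }
  out[on] <- spec$amplitude * (4 / pi) * vals
  out
}

#' @export
print.dbs_spec <- function(x, ...) {
  cat(sprintf(
    "<dbs_spec> target %s, amplitude %g a.u., frequency %g Hz (%s, n_max %d%s)\n",
    x$target, x$amplitude, x$frequency,
    if (x$waveform == "series") "truncated series" else "ideal square wave",
    x$n_max,
    if (x$onset > 0) sprintf(", onset %g s", x$onset) else ""))
  invisible(x)
}
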