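#' Sigmoid response-function constants
#'
#' Constants of the monotone sigmoid response functions \eqn{Z_e} and
#' \eqn{Z_i} that map average membrane drive to the active fraction of an
#' excitatory or inhibitory population:
#' \deqn{Z_p(x) = \frac{1}{1+e^{-b_p(x-\theta_p)}} - \frac{1}{1+e^{b_p\theta_p}},}
#' with slope \eqn{b_p} and threshold \eqn{\theta_p}.  The subtracted
#' constant pins \eqn{Z_p(0) = 0}, so the origin is a fixed point of the
#' unforced network.
#'
#' The defaults are the two classical Wilson-Cowan limit-cycle sigmoid
#' constant pairs, (slope 2.0, threshold 3.7) and (slope 1.3, threshold
#' 4.0), assigned to the excitatory and inhibitory roles respectively.
#' This assignment is the one under which the network reproduces its three
#' reference regimes (gamma at ~44 Hz, tremor at ~4 Hz, beta at ~20 Hz);
#' the same two constant pairs are sometimes quoted with the slope and
#' threshold symbols, or the e/i labels, interchanged, which yields
#' qualitatively different dynamics (see the methods vignette).
#'
#' The ceilings \eqn{k_e}, \eqn{k_i} are the suprema of the response
#' functions; for consistency they should equal
#' \eqn{1 - 1/(1+e^{b_p\theta_p})} (0.9994 and 0.9945 for the default
#' pairs), and a deviation beyond 5e-4 raises a warning (checked, not
#' enforced, so deliberately detuned ceilings remain expressible).
#'
#' @param theta_e,theta_i sigmoid thresholds (a.u.).
#' @param b_e,b_i sigmoid slopes (1/a.u.); must be positive.
#' @param k_e,k_i excitatory/inhibitory activity ceilings, in (0, 1).
#'
#' @return An object of class \code{sigmoid_params}.
#' @examples
#' sg <- sigmoid_params()
#' response_function(3.7, "e", sg)  # half-height point of Z_e
#' @export
sigmoid_params <- function(theta_e = 3.7, b_e = 2.0, theta_i = 4.0,
                           b_i = 1.3, k_e = 0.9994, k_i = 0.9945) {
  vals <- c(theta_e = theta_e, b_e = b_e, theta_i = theta_i, b_i = b_i,
            k_e = k_e, k_i = k_i)
  if (!all(is.finite(vals)))
    stop("sigmoid constants must be finite", call. = FALSE)
  if (b_e <= 0 || b_i <= 0)
    stop("sigmoid slopes b_e, b_i must be positive", call. = FALSE)
  if (k_e <= 0 || k_e >= 1 || k_i <= 0 || k_i >= 1)
    stop("ceilings k_e, k_i must lie in (0, 1)", call. = FALSE)
  for (p in c("e", "i")) {
    b <- vals[[paste0("b_", p)]]
    th <- vals[[paste0("theta_", p)]]
    k <- vals[[paste0("k_", p)]]
    implied <- 1 - 1 / (1 + exp(b * th))
    if (abs(k - implied) > 5e-4)
      warning(sprintf(
        "k_%s = %.4f differs from 1 - 1/(1+exp(b_%s*theta_%s)) = %.4f by more than 5e-4",
        p, k, p, p, implied), call. = FALSE)
  }
  structure(as.list(vals), class = "sigmoid_params")
}

#' Network parameter set
#'
#' Bundles the 11 connection-weight magnitudes, the external drive to the
#' deep cerebellar nuclei, the per-population time constants and the sigmoid
#' constants.  Weights are magnitudes: the sign of every connection is fixed
#' by the network equations (inhibitory inputs enter with a minus sign), so
#' a negative weight is rejected rather than reinterpreted.
#'
#' @param w numeric vector of 11 non-negative connection weights, in the
#'   order \code{w1..w11}; see \code{\link{weight_roles}} for the anatomical
#'   role of each.  Names, if present, must be \code{w1..w11}.
#' @param ext non-negative external (ascending) drive to the DCN population
#'   (a.u.).
#' @param tau_ms membrane time constant(s) in milliseconds; a scalar is
#'   recycled to all seven populations.  Stored internally in seconds.
#' @param sigmoid a \code{\link{sigmoid_params}} object.
#'
#' @return An object of class \code{wc_params} with elements \code{w}
#'   (named numeric, 11), \code{ext}, \code{tau_s} (named numeric, 7,
#'   seconds) and \code{sigmoid}.
#' @seealso \code{\link{wc_preset}} for the three named regime presets.
#' @examples
#' p <- wc_params(w = c(20, 5, 8, 25, 15, 5, 19, 5, 15, 20, 20), ext = 3.42)
#' p
#' @export
wc_params <- function(w, ext, tau_ms = 10, sigmoid = sigmoid_params()) {
  w <- as.numeric(w)
  if (length(w) != 11L || !all(is.finite(w)))
    stop("'w' must be 11 finite connection weights (w1..w11)", call. = FALSE)
  if (any(w < 0))
    stop("connection weights are magnitudes and must be non-negative; ",
         "polarity is fixed by the network equations", call. = FALSE)
  names(w) <- WEIGHT_NAMES
  if (!is.numeric(ext) || length(ext) != 1L || !is.finite(ext) || ext < 0)
    stop("'ext' must be a single non-negative number", call. = FALSE)
  if (length(tau_ms) == 1L) tau_ms <- rep(tau_ms, 7L)
  if (length(tau_ms) != 7L || any(!is.finite(tau_ms)) || any(tau_ms <= 0))
    stop("'tau_ms' must be one positive time constant, or seven", call. = FALSE)
  if (!inherits(sigmoid, "sigmoid_params"))
    stop("'sigmoid' must be a sigmoid_params object", call. = FALSE)
  structure(
    list(w = w, ext = as.numeric(ext),
         tau_s = setNames(tau_ms / 1000, POPULATIONS),
         sigmoid = sigmoid),
    class = "wc_params")
}

#' Anatomical role of each connection weight
#'
#' @return Named character vector mapping \code{w1..w11} to
#'   \code{"presynaptic -> postsynaptic"} descriptions.
#' @export
weight_roles <- function() WEIGHT_ROLES

# The three regime presets.  Column order: w1..w11, then ext.
.PRESETS <- list(
  healthy = list(w = c(20, 5, 8, 25, 15, 5, 19, 5, 15, 20, 20), ext = 3.42),
  tremor  = list(w = c(20, 12, 8, 9, 15, 5, 5, 5, 15, 20, 20),  ext = 3.42),
  beta    = list(w = c(20, 5, 8, 20, 15, 5, 5, 5, 15, 20, 20),  ext = 3.42)
)

#' Named regime presets
#'
#' Returns the parameter set of one of the three reference network regimes:
#' \describe{
#'   \item{\code{"healthy"}}{gamma-band limit cycle (~44 Hz) taken as the
#'     physiological, pro-kinetic state;}
#'   \item{\code{"tremor"}}{tremor-band limit cycle (~4 Hz), the
#'     essential-tremor / parkinsonian-tremor regime, reached from the
#'     healthy preset by raising corticothalamic feedback (w2) and lowering
#'     the cerebellar drive to the thalamus (w4) and the STN-to-GPe weight
#'     (w7);}
#'   \item{\code{"beta"}}{beta-band limit cycle (~20 Hz), the hypokinetic
#'     parkinsonian regime, reached from the tremor preset by lowering w2
#'     and raising w4.}
#' }
#' All presets share \code{ext = 3.42} and 10 ms time constants.
#'
#' @param name one of \code{"healthy"}, \code{"tremor"}, \code{"beta"}.
#' @param tau_ms,sigmoid passed to \code{\link{wc_params}}.
#' @return A \code{\link{wc_params}} object.
#' @examples
#' wc_preset("tremor")$w[["w7"]]  # 5
#' @export
wc_preset <- function(name, tau_ms = 10, sigmoid = sigmoid_params()) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.PRESETS))
    stop("unknown preset ", deparse(name), "; valid presets are: ",
         paste(sQuote(names(.PRESETS)), collapse = ", "), call. = FALSE)
  p <- .PRESETS[[name]]
  out <- wc_params(p$w, p$ext, tau_ms = tau_ms, sigmoid = sigmoid)
  attr(out, "preset") <- name
  out
}

#' Replace one parameter of a parameter set
#'
#' Convenience used by the sweep drivers: returns a copy of \code{params}
#' with a single entry (\code{"w1"}..\code{"w11"} or \code{"ext"}) replaced.
#'
#' @param params a \code{wc_params} object.
#' @param name parameter identifier.
#' @param value new non-negative value.
#' @return A \code{wc_params} object.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "wc_params"))
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c(WEIGHT_NAMES, "ext"))
    stop("unknown parameter ", deparse(name),
         "; valid names are w1..w11 and 'ext'", call. = FALSE)
  if (name == "ext") {
    wc_params(params$w, value, tau_ms = params$tau_s * 1000,
              sigmoid = params$sigmoid)
  } else {
    w <- params$w
    w[[name]] <- value
    wc_params(w, params$ext, tau_ms = params$tau_s * 1000,
              sigmoid = params$sigmoid)
  }
}

#' Extract the flat parameter vector
#'
#' @param object a \code{wc_params} object.
#' @param ... unused.
#' @return Named numeric vector \code{w1..w11, ext}.
#' @export
coef.wc_params <- function(object, ...) c(object$w, ext = object$ext)

#' @export
print.wc_params <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("<wc_params>",
      if (!is.null(preset)) paste0(" preset: ", preset), "\n", sep = "")
  wline <- paste(sprintf("%s=%g", names(x$w), x$w), collapse = " ")
  cat("  weights: ", wline, "\n", sep = "")
  cat(sprintf("  ext = %g (a.u.), tau = %s ms\n", x$ext,
              paste(unique(x$tau_s * 1000), collapse = "/")))
  sg <- x$sigmoid
  cat(sprintf("  sigmoid: theta_e=%g b_e=%g k_e=%g | theta_i=%g b_i=%g k_i=%g\n",
              sg$theta_e, sg$b_e, sg$k_e, sg$theta_i, sg$b_i, sg$k_i))
  invisible(x)
}
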