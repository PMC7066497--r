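#' Sigmoid population response function
#'
#' Active fraction of a population as a function of its summed membrane
#' drive:
#' \deqn{Z_p(x) = \frac{1}{1+e^{-b_p(x-\theta_p)}} - \frac{1}{1+e^{b_p\theta_p}},}
#' with \eqn{p = e} (excitatory) or \eqn{p = i} (inhibitory).  Strictly
#' increasing, zero at \eqn{x = 0}, and bounded above by
#' \eqn{1 - 1/(1+e^{b_p\theta_p})} (the ceiling \eqn{k_p} up to rounding of
#' the printed constants).
#'
#' @param x membrane drive (a.u.); vectorized, must be finite.
#' @param polarity \code{"e"} or \code{"i"}.
#' @param sigmoid a \code{\link{sigmoid_params}} object.
#' @return Numeric vector of activity fractions, same length as \code{x}.
#' @export
response_function <- function(x, polarity = c("e", "i"),
                              sigmoid = sigmoid_params()) {
  polarity <- match.arg(polarity)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite", call. = FALSE)
  b <- if (polarity == "e") sigmoid$b_e else sigmoid$b_i
  th <- if (polarity == "e") sigmoid$theta_e else sigmoid$theta_i
  1 / (1 + exp(-b * (x - th))) - 1 / (1 + exp(b * th))
}

#' Synaptic drive (sigmoid argument) of each population
#'
#' The bracketed argument passed to the response function of each
#' population, given the current network state:
#' \itemize{
#'   \item Cx:  \code{w1*Th}
#'   \item Th:  \code{w2*Cx - w3*nRT + w4*DCN - w5*GPi}
#'   \item nRT: \code{w6*Cx}
#'   \item DCN: \code{ext}
#'   \item GPe: \code{w7*STN - w8*GPe}
#'   \item GPi: \code{w9*STN}
#'   \item STN: \code{w10*Cx - w11*GPe}
#' }
#' A DBS forcing value, when present, adds to the drive of the stimulated
#' population only (inside the sigmoid argument).
#'
#' @param state numeric state vector of length 7 in population order.
#' @param params a \code{\link{wc_params}} object.
#' @param dbs_value forcing value (a.u.) added to the target's drive.
#' @param dbs_target population name receiving the forcing, or \code{NULL}.
#' @return Named numeric vector of length 7 (sigmoid arguments, a.u.).
#' @export
synaptic_drives <- function(state, params, dbs_value = 0, dbs_target = NULL) {
  stopifnot(inherits(params, "wc_params"))
  state <- as.numeric(state)
  if (length(state) != 7L || any(!is.finite(state)))
    stop("'state' must be 7 finite activity values", call. = FALSE)
  w <- unname(params$w)
  s <- setNames(state, POPULATIONS)
  drives <- c(
    Cx  = w[1] * s[["Th"]],
    Th  = w[2] * s[["Cx"]] - w[3] * s[["nRT"]] +
          w[4] * s[["DCN"]] - w[5] * s[["GPi"]],
    nRT = w[6] * s[["Cx"]],
    DCN = params$ext,
    GPe = w[7] * s[["STN"]] - w[8] * s[["GPe"]],
    GPi = w[9] * s[["STN"]],
    STN = w[10] * s[["Cx"]] - w[11] * s[["GPe"]])
  if (!is.null(dbs_target)) {
    if (!dbs_target %in% POPULATIONS)
      stop("unknown DBS target ", deparse(dbs_target),
           "; populations are: ", paste(POPULATIONS, collapse = ", "),
           call. = FALSE)
    drives[[dbs_target]] <- drives[[dbs_target]] + dbs_value
  }
  drives
}

#' Time derivative of the network state
#'
#' Right-hand side of the seven coupled population equations
#' \deqn{\tau_i \dot a_i = -a_i + (k_{p(i)} - a_i)\, Z_{p(i)}(\mathrm{drive}_i),}
#' in units of 1/second (time constants are stored in seconds).  This is
#' the reference R implementation; \code{\link{simulate_network}} integrates
#' an equivalent compiled version, and the agreement of the two is part of
#' the test suite.
#'
#' @param t time (seconds); only used to evaluate the DBS waveform.
#' @param state numeric state vector of length 7.
#' @param params a \code{\link{wc_params}} object.
#' @param dbs a \code{\link{dbs_spec}} or \code{NULL}.
#' @return Named numeric vector of derivatives (1/seconds).
#' @export
network_derivatives <- function(t, state, params, dbs = NULL) {
  dval <- 0
  target <- NULL
  if (!is.null(dbs)) {
    stopifnot(inherits(dbs, "dbs_spec"))
    dval <- dbs_waveform(t, dbs)
    target <- dbs$target
  }
  drives <- synaptic_drives(state, params, dbs_value = dval,
                            dbs_target = target)
  sg <- params$sigmoid
  k <- ifelse(EXCITATORY, sg$k_e, sg$k_i)
  z <- numeric(7L)
  z[EXCITATORY] <- response_function(drives[EXCITATORY], "e", sg)
  z[!EXCITATORY] <- response_function(drives[!EXCITATORY], "i", sg)
  a <- setNames(as.numeric(state), POPULATIONS)
  (-a + (k - a) * z) / params$tau_s
}

#' Closed-form DCN equilibrium
#'
#' The DCN equation decouples from the rest of the network (its drive is
#' the constant \code{ext}), so its activity converges to the fixed point
#' \deqn{E^* = \frac{k_e\, Z_e(\mathrm{ext})}{1 + Z_e(\mathrm{ext})}.}
#'
#' @param params a \code{\link{wc_params}} object.
#' @return The scalar equilibrium activity of the DCN population.
#' @export
dcn_equilibrium <- function(params) {
  z <- response_function(params$ext, "e", params$sigmoid)
  params$sigmoid$k_e * z / (1 + z)
}

#' Default initial state
#'
#' The model's source does not pin initial conditions; the package default
#' starts every population at 0.1 (interior of the invariant box
#' \eqn{[0,k_e]/[0,k_i]}).  The \code{"uniform"} policy draws each
#' population independently from \eqn{U(0.05, 0.2)} under the given seed;
#' the limit-cycle frequency is insensitive to the choice (a tested
#' property).
#'
#' @param policy \code{"fixed"} (all 0.1) or \code{"uniform"}.
#' @param seed integer seed used by the \code{"uniform"} policy.
#' @return Named numeric state vector of length 7.
#' @export
initial_state <- function(policy = c("fixed", "uniform"), seed = NULL) {
  policy <- match.arg(policy)
  if (policy == "fixed") return(setNames(rep(0.1, 7L), POPULATIONS))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  setNames(runif(7L, 0.05, 0.2), POPULATIONS)
}
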