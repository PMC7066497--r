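#' Simulation configuration
#'
#' Numerical settings for one integration of the network.  The default
#' integrator is an adaptive stiff solver (\code{deSolve}'s \code{lsoda}
#' with the maximum step clamped to the output step); a fixed-step
#' classical Runge-Kutta scheme at the same 0.1 ms step is available as
#' \code{"rk4"} and is used as the cross-check oracle and for large sweeps.
#'
#' @param duration simulated time (seconds, > 0).
#' @param dt_output output sampling step (seconds); also the step of the
#'   fixed-step \code{"rk4"} integrator.  Must satisfy
#'   \code{dt_output <= duration / 10}.
#' @param initial_state numeric state vector of length 7, or \code{NULL} to
#'   use the \code{init_policy}.
#' @param init_policy \code{"fixed"} (all populations at 0.1) or
#'   \code{"uniform"} (seeded draw in [0.05, 0.2]); see
#'   \code{\link{initial_state}}.
#' @param integrator \code{"lsoda"} (adaptive stiff, default) or
#'   \code{"rk4"} (fixed step).
#' @param rtol,atol relative/absolute solver tolerances (adaptive only).
#' @param hmax maximum internal step of the adaptive solver (seconds).
#' @param seed integer seed, used only by the \code{"uniform"} initial
#'   state policy.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(duration = 1, dt_output = 1e-4, initial_state = NULL,
                       init_policy = c("fixed", "uniform"),
                       integrator = c("lsoda", "rk4"),
                       rtol = 1e-6, atol = 1e-9, hmax = 1e-4, seed = NULL) {
  init_policy <- match.arg(init_policy)
  integrator <- match.arg(integrator)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a single positive time (seconds)", call. = FALSE)
  if (!is.numeric(dt_output) || length(dt_output) != 1L || dt_output <= 0 ||
      dt_output > duration / 10)
    stop("'dt_output' must be positive and at most duration/10",
         call. = FALSE)
  if (!is.null(initial_state)) {
    initial_state <- as.numeric(initial_state)
    if (length(initial_state) != 7L || any(!is.finite(initial_state)))
      stop("'initial_state' must be 7 finite activity values", call. = FALSE)
    initial_state <- setNames(initial_state, POPULATIONS)
  }
  structure(list(duration = duration, dt_output = dt_output,
                 initial_state = initial_state, init_policy = init_policy,
                 integrator = integrator, rtol = rtol, atol = atol,
                 hmax = hmax, seed = seed),
            class = "sim_config")
}

# Flatten parameters + DBS spec into the 31-slot vector the compiled
# right-hand side expects (layout documented in src/dbsnet.c).
.pack_parms <- function(params, dbs = NULL) {
  sg <- params$sigmoid
  dv <- if (is.null(dbs)) c(0, 0, 0, 1, 0, 0) else
    c(match(dbs$target, POPULATIONS), dbs$amplitude, dbs$frequency,
      dbs$n_max, dbs$onset, as.integer(dbs$waveform == "ideal"))
  c(unname(params$w), params$ext, unname(params$tau_s),
    sg$theta_e, sg$b_e, sg$theta_i, sg$b_i, sg$k_e, sg$k_i, dv)
}

#' Simulate the network
#'
#' Integrates the seven coupled population equations over a uniform output
#' grid, optionally with a DBS forcing term added inside the sigmoid
#' argument of the stimulated population.
#'
#' @param params a \code{\link{wc_params}} object.
#' @param config a \code{\link{sim_config}}; defaults to 1 s at 0.1 ms
#'   output step with the adaptive stiff solver.
#' @param dbs a \code{\link{dbs_spec}} or \code{NULL} (no stimulation).
#' @param rhs \code{"compiled"} (default) uses the C right-hand side;
#'   \code{"R"} integrates \code{\link{network_derivatives}} directly
#'   (slow; retained as an independent check of the compiled code).
#' @return An object of class \code{wc_trajectory}: a list with
#'   \code{times} (seconds), \code{activity} (times x 7 matrix in
#'   population order), \code{params}, \code{dbs}, \code{config} and
#'   solver \code{diagnostics}.
#' @examples
#' traj <- simulate_network(wc_preset("tremor"))
#' traj
#' @export
simulate_network <- function(params, config = sim_config(), dbs = NULL,
                             rhs = c("compiled", "R")) {
  stopifnot(inherits(params, "wc_params"), inherits(config, "sim_config"))
  if (!is.null(dbs)) stopifnot(inherits(dbs, "dbs_spec"))
  rhs <- match.arg(rhs)

  y0 <- config$initial_state
  if (is.null(y0))
    y0 <- initial_state(config$init_policy, seed = config$seed)
  times <- seq(0, config$duration, by = config$dt_output)

  if (rhs == "compiled") {
    pv <- .pack_parms(params, dbs)
    out <- if (config$integrator == "lsoda") {
      deSolve::ode(y = y0, times = times, func = "dbsnet_derivs",
                   parms = pv, dllname = "dbsnet",
                   initfunc = "dbsnet_initmod", method = "lsoda",
                   rtol = config$rtol, atol = config$atol,
                   hmax = config$hmax, maxsteps = 50000)
    } else {
      deSolve::ode(y = y0, times = times, func = "dbsnet_derivs",
                   parms = pv, dllname = "dbsnet",
                   initfunc = "dbsnet_initmod", method = "rk4")
    }
  } else {
    fr <- function(t, y, p) list(unname(network_derivatives(t, y, params, dbs)))
    out <- if (config$integrator == "lsoda") {
      deSolve::ode(y = y0, times = times, func = fr, parms = NULL,
                   method = "lsoda", rtol = config$rtol, atol = config$atol,
                   hmax = config$hmax, maxsteps = 50000)
    } else {
      deSolve::ode(y = y0, times = times, func = fr, parms = NULL,
                   method = "rk4")
    }
  }

  act <- unclass(out)[, -1, drop = FALSE]
  if (nrow(act) != length(times) || any(!is.finite(act))) {
    bad <- if (nrow(act) < length(times)) times[nrow(act) + 1L] else
      times[which(!is.finite(act[, 1]))[1]]
    stop(sprintf("integration failed near t = %g s", bad), call. = FALSE)
  }
  colnames(act) <- POPULATIONS

  diag <- list(integrator = config$integrator)
  ist <- attr(out, "istate")
  if (!is.null(ist))
    diag <- c(diag, list(n_steps = ist[3], n_rhs_evals = ist[4]))

  structure(list(times = times, activity = act, params = params,
                 dbs = dbs, config = config, diagnostics = diag),
            class = "wc_trajectory")
}

#' @export
print.wc_trajectory <- function(x, ...) {
  fs <- 1 / x$config$dt_output
  cat(sprintf("<wc_trajectory> %g s of activity, %d samples at %g kHz\n",
              x$config$duration, length(x$times), fs / 1000))
  if (!is.null(x$dbs))
    cat(sprintf("  DBS: %s, %g a.u. at %g Hz\n", x$dbs$target,
                x$dbs$amplitude, x$dbs$frequency))
  fin <- round(x$activity[nrow(x$activity), ], 4)
  cat("  final state: ",
      paste(sprintf("%s=%g", names(fin), fin), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.wc_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$activity, check.names = FALSE)
}

#' Plot population activity traces
#'
#' @param x a \code{wc_trajectory}.
#' @param populations which populations to draw (default all seven).
#' @param window optional \code{c(from, to)} time window (seconds).
#' @param ... passed to \code{matplot}.
#' @export
plot.wc_trajectory <- function(x, populations = POPULATIONS,
                               window = NULL, ...) {
  populations <- match.arg(populations, POPULATIONS, several.ok = TRUE)
  keep <- rep(TRUE, length(x$times))
  if (!is.null(window))
    keep <- x$times >= window[1] & x$times <= window[2]
  cols <- hcl.colors(length(populations), "Dark 3")
  matplot(x$times[keep], x$activity[keep, populations, drop = FALSE],
          type = "l", lty = 1, col = cols,
          xlab = "time (s)", ylab = "active fraction", ...)
  legend("topright", legend = populations, col = cols, lty = 1,
         cex = 0.8, bty = "n")
  invisible(x)
}
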