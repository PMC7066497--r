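#' Survey configuration
#'
#' Settings for a random parameter survey: each simulation draws the 11
#' connection weights independently and uniformly from
#' \code{weight_range} and the ascending drive from \code{ext_range},
#' under one seeded generator with a fixed draw order (w1..w11, then ext),
#' so record tables are exactly reproducible.
#'
#' @param n_sims number of simulations (>= 1).
#' @param weight_range numeric \code{c(lower, upper)} applied to every
#'   weight (default [0, 30]), or an 11 x 2 matrix of per-weight ranges;
#'   zero-width ranges pin parameters to fixed values.
#' @param ext_range numeric \code{c(lower, upper)} for the ascending drive
#'   (default [0, 10]).
#' @param seed integer RNG seed.
#' @return An object of class \code{survey_config}.
#' @export
survey_config <- function(n_sims, weight_range = c(0, 30),
                          ext_range = c(0, 10), seed = 1L) {
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1)
    stop("'n_sims' must be >= 1", call. = FALSE)
  if (is.matrix(weight_range)) {
    if (!identical(dim(weight_range), c(11L, 2L)) ||
        any(weight_range[, 1] > weight_range[, 2]))
      stop("matrix 'weight_range' must be 11 x 2 with lower <= upper",
           call. = FALSE)
  } else {
    if (length(weight_range) != 2L || weight_range[1] > weight_range[2])
      stop("'weight_range' must be c(lower, upper) with lower <= upper",
           call. = FALSE)
    weight_range <- matrix(rep(weight_range, each = 11L), ncol = 2L)
  }
  if (length(ext_range) != 2L || ext_range[1] > ext_range[2])
    stop("'ext_range' must be c(lower, upper) with lower <= upper",
         call. = FALSE)
  structure(list(n_sims = as.integer(n_sims), weight_range = weight_range,
                 ext_range = ext_range, seed = as.integer(seed)),
            class = "survey_config")
}

# Default numerical protocol for the experiment battery: 4 s of activity,
# second half analysed, fixed-step RK4 at the 0.1 ms output step (the
# adaptive solver agrees to < 1e-3 and is the default for single runs; the
# fixed-step scheme keeps large sweeps cheap and strictly deterministic).
sweep_sim_config <- function(duration = 4) {
  sim_config(duration = duration, integrator = "rk4")
}

# One result row shared by every sweep/survey driver.
.record_row <- function(params, summ, label, dbs = NULL, suppressed = NA,
                        baseline_frequency = NA_real_) {
  amp <- as.list(setNames(unname(summ$amplitude),
                          paste0("amp_", names(summ$amplitude))))
  base <- as.list(c(params$w, ext = params$ext))
  dbs_cols <- if (is.null(dbs))
    list(dbs_target = NA_character_, dbs_amplitude = NA_real_,
         dbs_frequency = NA_real_)
  else
    list(dbs_target = dbs$target, dbs_amplitude = dbs$amplitude,
         dbs_frequency = dbs$frequency)
  as.data.frame(c(base, dbs_cols,
                  list(oscillatory = summ$oscillatory,
                       dominant_frequency = summ$dominant_frequency,
                       state_label = label,
                       suppressed = suppressed,
                       baseline_frequency = baseline_frequency),
                  amp))
}

.bind_records <- function(rows, kind, meta = list()) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sweep_kind") <- kind
  attr(out, "meta") <- meta
  class(out) <- c("sweep_records", "data.frame")
  out
}

#' Random parameter survey
#'
#' Runs \code{config$n_sims} simulations at independently drawn random
#' parameter vectors and records, for each, the oscillation flag, dominant
#' frequency, state label and per-population amplitudes.  Trajectories are
#' summarized and discarded one at a time, so memory use is flat in
#' \code{n_sims}.
#'
#' @param config a \code{\link{survey_config}}.
#' @param sim a \code{\link{sim_config}}; the default uses 2 s of activity
#'   with the fixed-step integrator, enough to classify oscillation and
#'   place the dominant frequency on a 0.25 Hz grid while keeping large
#'   surveys tractable.
#' @param settings a \code{\link{spectral_settings}} object.
#' @param bands a \code{\link{band_table}}.
#' @param progress print a progress line every this many simulations
#'   (0 = silent).
#' @return A \code{sweep_records} data frame, one row per simulation.
#' @export
random_survey <- function(config, sim = sweep_sim_config(duration = 2),
                          settings = spectral_settings(),
                          bands = band_table(), progress = 0) {
  stopifnot(inherits(config, "survey_config"), inherits(sim, "sim_config"))
  set.seed(config$seed)
  rows <- vector("list", config$n_sims)
  for (i in seq_len(config$n_sims)) {
    w <- runif(11L, config$weight_range[, 1], config$weight_range[, 2])
    ext <- runif(1L, config$ext_range[1], config$ext_range[2])
    p <- wc_params(w, ext)
    traj <- simulate_network(p, sim)
    summ <- spectral_summary(traj, settings, keep_psd = FALSE)
    rows[[i]] <- .record_row(p, summ, classify_state(summ, bands = bands))
    if (progress > 0 && i %% progress == 0)
      message(sprintf("survey: %d / %d", i, config$n_sims))
  }
  .bind_records(rows, "survey",
                meta = list(config = unclass(config),
                            sim = unclass(sim)))
}

#' Single-parameter sweep
#'
#' Re-simulates the network for each value of one parameter, all other
#' parameters held at \code{base}.
#'
#' @param base a \code{\link{wc_params}} object.
#' @param name parameter to vary: \code{"w1"}..\code{"w11"} or
#'   \code{"ext"}.
#' @param grid numeric vector of values (finite, non-negative).
#' @param sim a \code{\link{sim_config}}; default 4 s, fixed-step.
#' @param settings a \code{\link{spectral_settings}} object.
#' @param bands a \code{\link{band_table}}.
#' @return A \code{sweep_records} data frame with one row per grid value,
#'   plus columns \code{param} and \code{value}.
#' @export
single_param_sweep <- function(base, name, grid,
                               sim = sweep_sim_config(),
                               settings = spectral_settings(),
                               bands = band_table()) {
  stopifnot(inherits(base, "wc_params"))
  if (!all(is.finite(grid))) stop("'grid' must be finite", call. = FALSE)
  rows <- lapply(grid, function(v) {
    p <- set_param(base, name, v)   # validates 'name'
    traj <- simulate_network(p, sim)
    summ <- spectral_summary(traj, settings, keep_psd = FALSE)
    cbind(data.frame(param = name, value = v),
          .record_row(p, summ, classify_state(summ, bands = bands)))
  })
  .bind_records(rows, "single_param", meta = list(param = name, grid = grid))
}

#' Pairwise parameter sweep
#'
#' Re-simulates the network on the Cartesian grid of two parameters, all
#' others held at \code{base}.  Records are ordered with \code{name_a}
#' varying slowest (row-major in \code{grid_a} x \code{grid_b}).
#'
#' @param base a \code{\link{wc_params}} object.
#' @param name_a,name_b distinct parameter names (\code{w1..w11},
#'   \code{ext}).
#' @param grid_a,grid_b numeric grids for the two parameters.
#' @param sim,settings,bands as in \code{\link{single_param_sweep}}.
#' @return A \code{sweep_records} data frame with columns \code{param_a},
#'   \code{value_a}, \code{param_b}, \code{value_b} prepended.
#' @export
pairwise_sweep <- function(base, name_a, name_b, grid_a, grid_b,
                           sim = sweep_sim_config(),
                           settings = spectral_settings(),
                           bands = band_table()) {
  stopifnot(inherits(base, "wc_params"))
  if (identical(name_a, name_b))
    stop("'name_a' and 'name_b' must be distinct parameters", call. = FALSE)
  rows <- list()
  k <- 0L
  for (va in grid_a) for (vb in grid_b) {
    p <- set_param(set_param(base, name_a, va), name_b, vb)
    traj <- simulate_network(p, sim)
    summ <- spectral_summary(traj, settings, keep_psd = FALSE)
    k <- k + 1L
    rows[[k]] <- cbind(
      data.frame(param_a = name_a, value_a = va,
                 param_b = name_b, value_b = vb),
      .record_row(p, summ, classify_state(summ, bands = bands)))
  }
  .bind_records(rows, "pairwise",
                meta = list(param_a = name_a, param_b = name_b,
                            grid_a = grid_a, grid_b = grid_b))
}

#' DBS amplitude/frequency sweep
#'
#' Simulates the network once without stimulation (the baseline), then once
#' per (amplitude, frequency) pair with the square-wave input delivered to
#' \code{target}, classifying every stimulated run against the baseline.
#' Records are ordered with frequency varying slowest and amplitude
#' fastest.
#'
#' @param base a \code{\link{wc_params}} object.
#' @param target DBS target population (\code{"STN"}, \code{"Th"},
#'   \code{"GPi"}, \code{"GPe"}).
#' @param amplitudes amplitude grid (a.u.); default 0..10 in steps of 1.
#' @param frequencies frequency grid (Hz); default 120 Hz only.
#' @param n_max,onset,waveform passed to \code{\link{dbs_spec}}.
#' @param sim,settings,bands as in \code{\link{single_param_sweep}}.
#' @param suppression_fraction passed to \code{\link{is_suppressed}}.
#' @return A \code{sweep_records} data frame; the \code{suppressed} column
#'   holds the \code{\link{is_suppressed}} verdict against the baseline,
#'   and rows with amplitude 0 duplicate the baseline record.
#' @export
dbs_sweep <- function(base, target, amplitudes = 0:10, frequencies = 120,
                      n_max = 1001, onset = 0, waveform = "series",
                      sim = sweep_sim_config(),
                      settings = spectral_settings(),
                      bands = band_table(), suppression_fraction = 0.2) {
  stopifnot(inherits(base, "wc_params"))
  traj0 <- simulate_network(base, sim)
  base_summ <- spectral_summary(traj0, settings, keep_psd = FALSE)
  base_label <- classify_state(base_summ, bands = bands)
  rows <- list()
  k <- 0L
  for (f in frequencies) for (A in amplitudes) {
    k <- k + 1L
    if (A == 0) {
      rows[[k]] <- .record_row(base, base_summ, base_label,
                               dbs = list(target = target, amplitude = 0,
                                          frequency = f),
                               suppressed = FALSE,
                               baseline_frequency =
                                 base_summ$dominant_frequency)
      next
    }
    spec <- dbs_spec(target, amplitude = A, frequency = f, n_max = n_max,
                     onset = onset, waveform = waveform)
    traj <- simulate_network(base, sim, dbs = spec)
    summ <- spectral_summary(traj, settings, keep_psd = FALSE)
    rows[[k]] <- .record_row(
      base, summ,
      classify_state(summ, baseline = base_summ, bands = bands,
                     suppression_fraction = suppression_fraction),
      dbs = spec,
      suppressed = is_suppressed(summ, base_summ, suppression_fraction),
      baseline_frequency = base_summ$dominant_frequency)
  }
  .bind_records(rows, "dbs",
                meta = list(target = target, amplitudes = amplitudes,
                            frequencies = frequencies,
                            suppression_fraction = suppression_fraction,
                            baseline_frequency =
                              base_summ$dominant_frequency))
}

#' Locate a threshold along an ordered sweep
#'
#' Given records ordered along a single swept axis, returns the smallest
#' grid value from which the predicate holds for every larger value.  A
#' predicate that is satisfied somewhere but not from any point onward is
#' non-monotone: a warning reports the first crossing and \code{NA} is
#' returned (there is no stable threshold).
#'
#' @param records a \code{sweep_records} data frame (or any data frame).
#' @param predicate either the name of a logical column (for example
#'   \code{"suppressed"}) or a function mapping the records data frame to
#'   a logical vector.
#' @param value_col name of the column holding the swept grid value
#'   (default \code{"dbs_amplitude"}).
#' @return The threshold grid value, or \code{NA} if the predicate never
#'   holds (or holds only non-monotonically).
#' @export
find_threshold <- function(records, predicate,
                           value_col = "dbs_amplitude") {
  if (nrow(records) == 0L) stop("'records' is empty", call. = FALSE)
  sat <- if (is.character(predicate)) {
    if (!predicate %in% names(records))
      stop("no column ", sQuote(predicate), " in records", call. = FALSE)
    as.logical(records[[predicate]])
  } else {
    as.logical(predicate(records))
  }
  if (anyNA(sat)) stop("predicate returned NA", call. = FALSE)
  if (!value_col %in% names(records))
    stop("no column ", sQuote(value_col), " in records", call. = FALSE)
  vals <- records[[value_col]]
  if (!any(sat)) return(NA_real_)
  holds_onward <- rev(cumprod(rev(sat))) > 0
  first_cross <- which(sat)[1L]
  if (!any(holds_onward)) {
    warning(sprintf(
      "predicate satisfied non-monotonically (first crossing at %s = %g) but fails at the end of the grid; no stable threshold",
      value_col, vals[first_cross]), call. = FALSE)
    return(NA_real_)
  }
  k <- which(holds_onward)[1L]
  if (k != first_cross)
    warning(sprintf(
      "non-monotone satisfaction: first crossing at %s = %g, stable from %s = %g",
      value_col, vals[first_cross], value_col, vals[k]), call. = FALSE)
  vals[k]
}

#' @export
print.sweep_records <- function(x, ...) {
  kind <- attr(x, "sweep_kind")
  cat(sprintf("<sweep_records> %s, %d records\n", kind, nrow(x)))
  osc <- sum(x$oscillatory)
  cat(sprintf("  oscillatory: %d (%.1f%%)", osc, 100 * osc / nrow(x)))
  if (osc > 0)
    cat(sprintf("; dominant frequency %.2f-%.2f Hz",
                min(x$dominant_frequency, na.rm = TRUE),
                max(x$dominant_frequency, na.rm = TRUE)))
  cat("\n")
  print.data.frame(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
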