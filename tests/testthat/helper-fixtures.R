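# Shared fixtures.  Reference trajectories of the three presets are
# simulated once per test run (4 s, fixed-step RK4 at 0.1 ms) and cached;
# the adaptive solver agrees to < 1e-3 (itself a tested property), so the
# cheaper deterministic integrator is used for fixtures.

.fixture_cache <- new.env(parent = emptyenv())

preset_traj <- function(name, duration = 4) {
  key <- paste0(name, "_", duration)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_network(
      wc_preset(name), sim_config(duration = duration, integrator = "rk4"))
  .fixture_cache[[key]]
}

preset_summary <- function(name, duration = 4, reference = "Th") {
  key <- paste0("s_", name, "_", duration, "_", reference)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- spectral_summary(
      preset_traj(name, duration), reference = reference, keep_psd = FALSE)
  .fixture_cache[[key]]
}

# Minimal hand-built trajectory (for analysis-only tests): 'mat' is a
# times x 7 matrix in population order.
make_traj <- function(mat, dt = 1e-4) {
  times <- (seq_len(nrow(mat)) - 1) * dt
  structure(
    list(times = times,
         activity = `colnames<-`(mat, populations()),
         params = wc_preset("tremor"), dbs = NULL,
         config = sim_config(duration = max(times), dt_output = dt),
         diagnostics = list()),
    class = "wc_trajectory")
}

# trajectory whose 7 columns are copies of one signal
signal_traj <- function(x, dt = 1e-4) {
  make_traj(matrix(rep(x, 7), ncol = 7), dt = dt)
}

# common sampling grid for constructed-signal tests
fs <- 1e4
tt <- seq(0, 2, by = 1 / fs)[-1]

# bare table values, without the sweep/provenance attributes
record_values <- function(x) {
  x <- as.data.frame(x)
  for (a in c("meta", "sweep_kind", "provenance", "dbsnet_provenance"))
    attr(x, a) <- NULL
  x
}
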