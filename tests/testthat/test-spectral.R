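test_that("Welch spectrum locates a pure tone", {
  x <- sin(2 * pi * 20 * tt)
  psd <- power_spectrum(x, fs)
  expect_true(all(psd$power >= 0))
  expect_lte(psd$resolution, 0.25)
  expect_lt(abs(dominant_frequency(psd) - 20), psd$resolution)
  # cross-check the peak location against the raw periodogram
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - dominant_frequency(psd)), 1)
})

test_that("a constant signal has no dominant frequency", {
  psd <- power_spectrum(rep(0.3, 2000), fs)
  expect_true(is.na(dominant_frequency(psd)))
})

test_that("competing tones are ranked by power", {
  x <- 1.0 * sin(2 * pi * 4 * tt) + 0.1 * sin(2 * pi * 40 * tt)
  psd <- power_spectrum(x, fs)
  expect_equal(dominant_frequency(psd), 4, tolerance = 0.3)
  # both tones appear as local maxima, the 4 Hz one larger
  at <- function(f) max(psd$power[abs(psd$freq - f) < 0.5])
  expect_gt(at(4), at(40))
  expect_gt(at(40), 50 * stats::median(psd$power[psd$freq > 0.5]))
})

test_that("dominant frequency steps down to a strong fundamental", {
  # 2nd harmonic carries more power, but the 4 Hz fundamental is well
  # above the sub-harmonic ratio: the cycle rate must be reported
  x <- 0.6 * sin(2 * pi * 4 * tt) + 1.0 * sin(2 * pi * 8 * tt)
  expect_equal(dominant_frequency(power_spectrum(x, fs)), 4,
               tolerance = 0.3)
  # a weak sub-harmonic (power ratio 1e-4) must NOT capture the peak
  y <- 0.01 * sin(2 * pi * 4 * tt) + 1.0 * sin(2 * pi * 8 * tt)
  expect_equal(dominant_frequency(power_spectrum(y, fs)), 8,
               tolerance = 0.3)
})

test_that("multi-segment averaging is supported", {
  x <- sin(2 * pi * 30 * tt)
  st <- spectral_settings(n_segments = 4, overlap = 0.5)
  psd <- power_spectrum(x, fs, st)
  expect_lt(abs(dominant_frequency(psd) - 30), 0.5)
  expect_error(power_spectrum(x[1:32], fs), "64")
})

test_that("total spectral mass tracks signal variance", {
  mass <- vapply(c(0.1, 0.5, 1, 2), function(a) {
    sum(power_spectrum(a * sin(2 * pi * 10 * tt), fs)$power)
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("oscillation amplitude is peak-to-trough over the window", {
  x <- 0.2 + 0.15 * sin(2 * pi * 6 * tt)
  tr <- signal_traj(x)
  amp <- oscillation_amplitude(tr)
  expect_equal(unname(amp), rep(0.3, 7), tolerance = 1e-3)
  expect_equal(unname(oscillation_amplitude(signal_traj(rep(0.4, 2001)))),
               rep(0, 7))
})

test_that("the oscillation test accepts limit cycles and rejects decay", {
  expect_true(is_oscillatory(preset_traj("tremor")))
  expect_true(is_oscillatory(preset_traj("healthy")))
  dead <- simulate_network(wc_params(rep(0, 11), 0),
                           sim_config(duration = 1,
                                      initial_state = rep(0.4, 7)))
  expect_false(is_oscillatory(dead))
  # severing the thalamocortical drive abolishes the tremor oscillation
  cut <- simulate_network(set_param(wc_preset("tremor"), "w1", 0),
                          sim_config(duration = 4, integrator = "rk4"))
  expect_false(is_oscillatory(cut))
})

test_that("DCN amplitude is negligible after the transient", {
  for (nm in c("healthy", "tremor", "beta"))
    expect_lt(oscillation_amplitude(preset_traj(nm))[["DCN"]], 1e-3)
})

test_that("dominant frequency is stable under doubling the duration", {
  for (nm in c("healthy", "tremor", "beta")) {
    f4 <- preset_summary(nm)$dominant_frequency
    tr8 <- preset_traj(nm, duration = 8)
    f8 <- spectral_summary(tr8, reference = "Th",
                           keep_psd = FALSE)$dominant_frequency
    expect_lt(abs(f4 - f8), 0.25)
  }
})

test_that("phase ordering recovers a constructed delay", {
  f0 <- 5; T0 <- 1 / f0
  base <- 0.2 + 0.1 * sin(2 * pi * f0 * tt)
  lagd <- 0.2 + 0.1 * sin(2 * pi * f0 * (tt - T0 / 10))
  mat <- matrix(rep(base, 7), ncol = 7)
  mat[, 4] <- 0.3                      # DCN fixed
  mat[, 7] <- lagd                     # STN delayed by T/10
  tr <- make_traj(mat)
  ord <- phase_order(tr)
  expect_identical(ord[length(ord)], "STN")
  d <- attr(ord, "delay")
  expect_equal(unname(d[["STN"]]), T0 / 10, tolerance = 2e-4)
  # identical signals tie at zero delay
  expect_equal(unname(d[["Cx"]]), 0, tolerance = 2e-4)
  expect_error(phase_order(signal_traj(rep(0.2, 2001))), "oscillatory")
})

test_that("summary of a trajectory is its spectral summary", {
  s <- summary(preset_traj("beta"), reference = "Th")
  expect_s3_class(s, "wc_spectral_summary")
  expect_true(s$oscillatory)
  expect_true(s$dominant_frequency > 13 && s$dominant_frequency < 30)
  # dominant frequency lies on the PSD grid
  expect_true(any(abs(s$ref_psd$freq - s$dominant_frequency) < 1e-9))
})
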