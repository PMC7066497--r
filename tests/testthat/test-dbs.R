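test_that("DBS spec validation", {
  expect_error(dbs_spec("STN", amplitude = 5, frequency = 120, n_max = 1000),
               "odd")
  expect_error(dbs_spec("STN", amplitude = -1, frequency = 120),
               "non-negative")
  expect_error(dbs_spec("STN", amplitude = 5, frequency = 0), "positive")
  expect_error(dbs_spec("SNr", amplitude = 5, frequency = 120))
  expect_error(dbs_spec("STN", 5, 120, onset = -1), "non-negative")
})

test_that("square-wave series has the expected structure", {
  spec <- dbs_spec("STN", amplitude = 1, frequency = 120)
  # amplitude scaling: zero amplitude is identically zero
  z <- dbs_spec("STN", amplitude = 0, frequency = 120)
  expect_equal(dbs_waveform(seq(0, 0.05, by = 1e-4), z), rep(0, 501))

  # half-period antisymmetry of the odd-harmonic series
  t1 <- seq(0.001, 0.004, by = 1e-4)
  expect_equal(dbs_waveform(t1, spec) + dbs_waveform(t1 + 1 / 240, spec),
               rep(0, length(t1)), tolerance = 1e-10)

  # plateau midpoint of the truncated series is within 1e-2 of +-A
  expect_lt(abs(dbs_waveform(1 / 480, spec) - 1), 1e-2)
  expect_lt(abs(dbs_waveform(3 / 480, spec) + 1), 1e-2)
  a5 <- dbs_spec("Th", amplitude = 5, frequency = 80)
  expect_lt(abs(dbs_waveform(1 / 320, a5) - 5), 5e-2)

  # no DC component: mean over one period vanishes
  tt <- seq(0, 1 / 120, length.out = 24001)
  w <- dbs_waveform(tt, spec)
  expect_lt(abs(mean((w[-1] + w[-length(w)]) / 2)), 1e-10)

  # periodicity
  expect_equal(dbs_waveform(t1, spec), dbs_waveform(t1 + 1 / 120, spec),
               tolerance = 1e-9)
})

test_that("the truncated series converges to the ideal square wave", {
  f <- 120
  ser <- dbs_spec("STN", 1, f, n_max = 1001)
  sq <- dbs_spec("STN", 1, f, waveform = "ideal")
  # compare away from the discontinuities (middle 60% of each plateau)
  ph <- c(seq(0.1, 0.4, by = 0.01), seq(0.6, 0.9, by = 0.01))
  tt <- ph / f
  expect_lt(max(abs(dbs_waveform(tt, ser) - dbs_waveform(tt, sq))), 1e-2)
  # and a coarser truncation is visibly worse at the plateau edges
  ser51 <- dbs_spec("STN", 1, f, n_max = 51)
  expect_gt(max(abs(dbs_waveform(tt, ser51) - dbs_waveform(tt, sq))),
            max(abs(dbs_waveform(tt, ser) - dbs_waveform(tt, sq))))
})

test_that("stimulation is silent before its onset", {
  spec <- dbs_spec("STN", 1, 120, onset = 0.5)
  expect_equal(dbs_waveform(c(0, 0.2, 0.499), spec), rep(0, 3))
  ref <- dbs_spec("STN", 1, 120)
  expect_equal(dbs_waveform(0.5 + 1 / 480, spec),
               dbs_waveform(1 / 480, ref))
})

test_that("forcing enters only the targeted population's drive", {
  p <- wc_preset("tremor")
  st <- setNames(rep(0.2, 7), populations())
  spec <- dbs_spec("GPi", 3, 130)
  tq <- 1 / (4 * 130)  # quarter period: forcing ~ +3
  d0 <- network_derivatives(tq, st, p)
  d1 <- network_derivatives(tq, st, p, dbs = spec)
  changed <- names(which(abs(d1 - d0) > 1e-12))
  expect_identical(changed, "GPi")
})
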