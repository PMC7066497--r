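# Short simulations (1-2 s, fixed step) keep the sweep tests cheap; the
# full 4 s analysis protocol is exercised by the acceptance tests.
fast_sim <- sim_config(duration = 1, integrator = "rk4")

test_that("a degenerate sweep equals a direct simulation", {
  base <- wc_preset("tremor")
  rec <- single_param_sweep(base, "w7", grid = 5, sim = fast_sim)
  expect_equal(nrow(rec), 1L)
  tr <- simulate_network(base, fast_sim)
  s <- spectral_summary(tr, keep_psd = FALSE)
  expect_equal(rec$dominant_frequency, s$dominant_frequency)
  expect_equal(rec$oscillatory, s$oscillatory)
  expect_equal(unlist(rec[paste0("amp_", populations())]),
               s$amplitude, ignore_attr = TRUE)
  expect_error(single_param_sweep(base, "w99", 1:3, sim = fast_sim),
               "unknown parameter")
})

test_that("sweep records hold the full parameter vector", {
  base <- wc_preset("tremor")
  rec <- single_param_sweep(base, "w7", grid = c(5, 22), sim = fast_sim)
  expect_equal(rec$w7, c(5, 22))
  expect_equal(rec$value, c(5, 22))
  for (nm in setdiff(paste0("w", 1:11), "w7"))
    expect_equal(rec[[nm]], rep(base$w[[nm]], 2))
  expect_equal(rec$ext, rep(3.42, 2))
  # the frequency column is populated exactly for oscillatory records
  expect_identical(is.na(rec$dominant_frequency), !rec$oscillatory)
})

test_that("pairwise sweeps cover the grid in deterministic order", {
  base <- wc_preset("tremor")
  rec <- pairwise_sweep(base, "w4", "w5", grid_a = c(9, 12),
                        grid_b = c(10, 15, 20), sim = fast_sim)
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$value_a, rep(c(9, 12), each = 3))
  expect_equal(rec$value_b, rep(c(10, 15, 20), 2))
  expect_equal(rec$w4, rec$value_a)
  expect_equal(rec$w5, rec$value_b)
  expect_error(pairwise_sweep(base, "w4", "w4", 1:2, 1:2), "distinct")
  # 1x1 grid at the base values equals the direct run
  one <- pairwise_sweep(base, "w4", "w5", 9, 15, sim = fast_sim)
  direct <- spectral_summary(simulate_network(base, fast_sim),
                             keep_psd = FALSE)
  expect_equal(one$dominant_frequency, direct$dominant_frequency)
})

test_that("surveys are reproducible and draw in a fixed order", {
  cfg <- survey_config(n_sims = 6, seed = 99)
  r1 <- random_survey(cfg, sim = fast_sim)
  r2 <- random_survey(cfg, sim = fast_sim)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 6L)
  # draw order is w1..w11 then ext, one generator
  set.seed(99)
  w <- runif(11, 0, 30); e <- runif(1, 0, 10)
  expect_equal(unlist(r1[1, paste0("w", 1:11)]), w, ignore_attr = TRUE)
  expect_equal(r1$ext[1], e)
  # a different seed gives different parameters
  r3 <- random_survey(survey_config(n_sims = 6, seed = 100), sim = fast_sim)
  expect_false(identical(r1$w1, r3$w1))
})

test_that("zero-width survey ranges pin the parameter vector", {
  tremor <- wc_preset("tremor")
  cfg <- survey_config(n_sims = 3,
                       weight_range = cbind(tremor$w, tremor$w),
                       ext_range = c(3.42, 3.42), seed = 5)
  rec <- random_survey(cfg, sim = sweep_sim_config(duration = 4))
  expect_equal(nrow(unique(as.data.frame(rec))), 1L)
  expect_true(all(rec$state_label == "tremor_band"))
})

test_that("DBS sweeps classify against their own baseline", {
  base <- wc_preset("tremor")
  rec <- dbs_sweep(base, "STN", amplitudes = c(0, 1), frequencies = 120,
                   sim = fast_sim)
  expect_equal(nrow(rec), 2L)
  # the zero-amplitude record is the unstimulated network
  direct <- spectral_summary(simulate_network(base, fast_sim),
                             keep_psd = FALSE)
  expect_equal(rec$dominant_frequency[rec$dbs_amplitude == 0],
               direct$dominant_frequency)
  expect_false(rec$suppressed[1])
  expect_equal(rec$baseline_frequency,
               rep(direct$dominant_frequency, 2))
})

test_that("find_threshold locates stable onsets and flags non-monotone ones", {
  rec <- data.frame(dbs_amplitude = 1:8,
                    suppressed = c(F, F, F, T, T, T, T, T))
  expect_equal(find_threshold(rec, "suppressed"), 4)
  # predicate as a function
  expect_equal(find_threshold(rec, function(d) d$dbs_amplitude >= 6), 6)
  # always true: first grid value
  expect_equal(find_threshold(rec, function(d) rep(TRUE, nrow(d))), 1)
  # never true: none
  expect_true(is.na(find_threshold(rec, function(d) rep(FALSE, nrow(d)))))
  # non-monotone but stable from 5: warn, report the stable onset
  rec$odd <- c(F, T, F, F, T, T, T, T)
  expect_warning(th <- find_threshold(rec, "odd"), "non-monotone")
  expect_equal(th, 5)
  # satisfied somewhere but failing at the end: no stable threshold
  rec$fail <- c(F, T, T, F, F, F, F, F)
  expect_warning(th2 <- find_threshold(rec, "fail"), "no stable threshold")
  expect_true(is.na(th2))
  expect_error(find_threshold(rec[0, ], "suppressed"), "empty")
  expect_error(find_threshold(rec, "nope"), "no column")
})

test_that("sweep records and direct simulation agree at shared points", {
  base <- wc_preset("beta")
  rec <- single_param_sweep(base, "ext", grid = c(2, 3.42), sim = fast_sim)
  direct <- spectral_summary(
    simulate_network(set_param(base, "ext", 2), fast_sim),
    keep_psd = FALSE)
  expect_equal(rec$dominant_frequency[1], direct$dominant_frequency)
  expect_equal(rec$state_label[2],
               classify_state(spectral_summary(
                 simulate_network(base, fast_sim), keep_psd = FALSE)))
})
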