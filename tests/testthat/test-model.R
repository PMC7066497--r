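test_that("response function is zero at rest, increasing, and saturates at k", {
  sg <- sigmoid_params()
  expect_identical(response_function(0, "e", sg), 0)
  expect_identical(response_function(0, "i", sg), 0)
  # direct evaluation at the threshold: Z(theta) = 1/2 - 1/(1+exp(b*theta))
  expect_equal(response_function(sg$theta_e, "e", sg),
               0.5 - 1 / (1 + exp(sg$b_e * sg$theta_e)))
  expect_equal(response_function(sg$theta_i, "i", sg),
               0.5 - 1 / (1 + exp(sg$b_i * sg$theta_i)))
  # strictly increasing
  x <- seq(-5, 15, by = 0.25)
  expect_true(all(diff(response_function(x, "e", sg)) > 0))
  expect_true(all(diff(response_function(x, "i", sg)) > 0))
  # ceilings reached within 5e-4
  expect_lt(abs(response_function(100, "e", sg) - sg$k_e), 5e-4)
  expect_lt(abs(response_function(100, "i", sg) - sg$k_i), 5e-4)
  expect_error(response_function(NaN, "e", sg), "finite")
  expect_error(response_function(Inf, "e", sg), "finite")
})

test_that("synaptic drives follow the wiring diagram", {
  p <- wc_preset("tremor")
  # zero state: every drive vanishes except the constant DCN input
  d0 <- synaptic_drives(rep(0, 7), p)
  expect_equal(unname(d0), c(0, 0, 0, p$ext, 0, 0, 0))

  # hand evaluation of the GPe drive: w7*E_STN - w8*I_GPe with w7 = w8 = 5
  st <- setNames(rep(0, 7), populations())
  st[["STN"]] <- 0.5; st[["GPe"]] <- 0.2
  d <- synaptic_drives(st, p)
  expect_equal(d[["GPe"]], 5 * 0.5 - 5 * 0.2)

  # a DBS value adds to exactly one drive
  set.seed(1)
  st2 <- runif(7, 0, 0.5)
  for (amt in c(-2, 0.7)) {
    d1 <- synaptic_drives(st2, p)
    d2 <- synaptic_drives(st2, p, dbs_value = amt, dbs_target = "STN")
    expect_equal(d2[["STN"]] - d1[["STN"]], amt)
    expect_equal(d2[names(d2) != "STN"], d1[names(d1) != "STN"])
  }
  expect_error(synaptic_drives(st2, p, 1, "SNr"), "unknown DBS target")
})

test_that("origin is an equilibrium without external drive", {
  p <- wc_params(wc_preset("tremor")$w, ext = 0)
  expect_equal(unname(network_derivatives(0, rep(0, 7), p)), rep(0, 7))
})

test_that("DCN sits at its closed-form equilibrium", {
  p <- wc_preset("healthy")
  eq <- dcn_equilibrium(p)
  st <- setNames(rep(0.3, 7), populations())
  st[["DCN"]] <- eq
  expect_equal(network_derivatives(0, st, p)[["DCN"]], 0, tolerance = 1e-12)
})

test_that("zero-amplitude DBS leaves the derivatives unchanged", {
  p <- wc_preset("beta")
  st <- setNames(seq(0.05, 0.35, by = 0.05), populations())
  d0 <- network_derivatives(0.123, st, p)
  d1 <- network_derivatives(0.123, st, p,
                            dbs = dbs_spec("STN", 0, 120))
  expect_identical(d0, d1)
})

test_that("unforced, unconnected network decays monotonically to rest", {
  p <- wc_params(rep(0, 11), ext = 0)
  tr <- simulate_network(p, sim_config(duration = 0.5,
                                       initial_state = rep(0.4, 7)))
  for (pop in populations()) {
    x <- tr$activity[, pop]
    expect_true(all(diff(x) <= 1e-12))
    expect_lt(x[length(x)], 1e-4)
  }
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  p <- wc_preset("tremor")
  cfg <- sim_config(duration = 0.3, integrator = "rk4")
  t_c <- simulate_network(p, cfg)
  t_r <- simulate_network(p, cfg, rhs = "R")
  expect_lt(max(abs(t_c$activity - t_r$activity)), 1e-12)
  # and with the DBS forcing (exercises the harmonic recurrence in C
  # against the direct sine summation in R)
  spec <- dbs_spec("STN", 2, 120)
  t_c2 <- simulate_network(p, cfg, dbs = spec)
  t_r2 <- simulate_network(p, cfg, dbs = spec, rhs = "R")
  expect_lt(max(abs(t_c2$activity - t_r2$activity)), 1e-8)
})

test_that("adaptive stiff and fixed-step RK4 trajectories agree", {
  for (nm in c("healthy", "tremor", "beta")) {
    a <- simulate_network(wc_preset(nm), sim_config(duration = 1))
    b <- simulate_network(wc_preset(nm),
                          sim_config(duration = 1, integrator = "rk4"))
    expect_lt(max(abs(a$activity - b$activity)), 1e-3)
  }
})

test_that("tightening solver tolerances tenfold barely moves the endpoint", {
  p <- wc_preset("beta")
  a <- simulate_network(p, sim_config(duration = 1))
  b <- simulate_network(p, sim_config(duration = 1,
                                      rtol = 1e-7, atol = 1e-10))
  expect_lt(max(abs(a$activity[nrow(a$activity), ] -
                    b$activity[nrow(b$activity), ])), 1e-5)
})

test_that("trajectories stay inside the activity box", {
  sg <- sigmoid_params()
  set.seed(11)
  for (i in 1:5) {
    p <- wc_params(runif(11, 0, 30), runif(1, 0, 10))
    ic <- runif(7, 0.02, 0.9)
    ic[c(3, 5, 6)] <- pmin(ic[c(3, 5, 6)], sg$k_i)
    tr <- simulate_network(p, sim_config(duration = 1, initial_state = ic,
                                         integrator = "rk4"))
    kmax <- ifelse(populations() %in% c("nRT", "GPe", "GPi"),
                   sg$k_i, sg$k_e)
    expect_true(all(tr$activity >= -1e-6))
    expect_true(all(sweep(tr$activity, 2, kmax) <= 1e-6))
  }
})

test_that("the DCN trace is independent of every connection weight", {
  set.seed(21)
  p1 <- wc_params(runif(11, 0, 30), ext = 3.42)
  p2 <- wc_params(runif(11, 0, 30), ext = 3.42)
  cfg <- sim_config(duration = 0.5, integrator = "rk4")
  t1 <- simulate_network(p1, cfg)
  t2 <- simulate_network(p2, cfg)
  expect_identical(t1$activity[, "DCN"], t2$activity[, "DCN"])
  # and converges to the closed-form fixed point
  expect_lt(abs(t1$activity[nrow(t1$activity), "DCN"] -
                dcn_equilibrium(p1)), 1e-6)
})

test_that("limit-cycle frequency is robust to the initial state", {
  freqs <- vapply(1:5, function(s) {
    tr <- simulate_network(
      wc_preset("tremor"),
      sim_config(duration = 4, integrator = "rk4",
                 init_policy = "uniform", seed = s))
    spectral_summary(tr, reference = "Th",
                     keep_psd = FALSE)$dominant_frequency
  }, numeric(1))
  expect_lt(max(freqs) - min(freqs), 0.25)
})

test_that("simulation configuration is validated", {
  expect_error(sim_config(duration = 0), "positive")
  expect_error(sim_config(duration = 1, dt_output = 0.2), "duration/10")
  expect_error(sim_config(initial_state = rep(0.1, 6)), "7")
})
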