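p_default <- network_params()

test_that("synaptic kernel matches its closed form and the step function", {
  expect_equal(kernel_value(0), 0)
  expect_equal(kernel_value(-5), 0)
  expect_equal(kernel_value(3), (exp(-0.3) - exp(-1)) / 7)
  expect_equal(kernel_value(3), 0.053277, tolerance = 1e-5)
  taps <- kernel_taps()
  expect_equal(taps, kernel_value(1:10))
  expect_true(all(taps > 0))
})

test_that("a single spike echoes the kernel through the filter window", {
  bank <- filter_bank(1)
  bank <- filter_update(bank, 1L) # spike enters at t0; s(t0) still 0
  expect_equal(bank$s, 0)
  taps <- kernel_taps()
  for (tau in 1:10) {
    bank <- filter_update(bank, 0L)
    expect_equal(bank$s, taps[tau])
  }
  bank <- filter_update(bank, 0L)
  expect_equal(bank$s, 0) # decays to exactly zero after the window
})

test_that("filtering is linear: two spikes superpose and empty history is
          silent", {
  taps <- kernel_taps()
  bank <- filter_bank(2)
  bank <- filter_update(bank, c(1L, 0L))
  bank <- filter_update(bank, c(1L, 0L))
  bank <- filter_update(bank, c(0L, 0L))
  expect_equal(bank$s, c(taps[1] + taps[2], 0))
  expect_error(filter_update(bank, c(1L, 0L, 0L)), "spike bits")
})

test_that("dendritic potentials are the documented affine/linear maps", {
  expect_equal(basal_potential(matrix(0, 2, 3), rep(1, 3), c(0.3, 0.3)),
               c(0.3, 0.3))
  expect_equal(basal_potential(matrix(c(1, 2), 1, 2), c(0.5, 0.25), 0.1),
               1.1)
  expect_equal(basal_potential(diag(2), c(0, 0), c(1, 2)), c(1, 2))
  expect_error(basal_potential(diag(2), c(1, 2, 3), c(0, 0)), "dimension")
  expect_equal(apical_potential(diag(2), c(0.2, 0.4)), c(0.2, 0.4))
  expect_equal(apical_potential(matrix(c(0.5, -0.5), 1, 2), c(0.4, 0.2)),
               0.1)
  expect_error(apical_potential(diag(2), 1), "dimension")
})

test_that("somatic Euler steps reproduce hand-computed values and fixed
          points", {
  expect_equal(soma_step_hidden(0.5, 1, 0, p_default), 0.75)
  expect_equal(soma_step_hidden(0, 0, 0, p_default), 0) # resting fixed point
  expect_equal(soma_step_output(0, 1,
                                teaching_current(0, 1, 0, p_default),
                                p_default), 12.6)
  expect_equal(soma_step_output(0, 0, 0, p_default), 0)
})

test_that("teaching current follows the conductance form and vanishes in the
          forward phase", {
  expect_equal(teaching_current(0, 1, 0, p_default), 12)
  expect_equal(teaching_current(0, 0, 1, p_default), -12)
  expect_equal(teaching_current(3, 0, 0, p_default), 0)
  expect_equal(teaching_current(2, 0.5, 0.5, p_default),
               0.5 * (12 - 2) + 0.5 * (-12 - 2))
})

test_that("somatic voltages converge to their conductance-weighted steady
          states", {
  V <- 0
  for (t in 1:200) V <- soma_step_hidden(V, 1, 0, p_default)
  expect_equal(V, 0.6 / 0.7, tolerance = 1e-6)
  V <- 0
  for (t in 1:200) {
    V <- soma_step_output(V, 0, teaching_current(V, 1, 0, p_default),
                          p_default)
  }
  expect_equal(V, 12 / 1.7, tolerance = 1e-6)
})

test_that("voltages stay bounded by drive and rest over long runs", {
  set.seed(4)
  V <- 0.3
  B <- 2
  hi <- 0
  for (t in 1:1e5) {
    V <- soma_step_hidden(V, runif(1, -B, B), runif(1, -B, B), p_default)
    hi <- max(hi, abs(V))
  }
  expect_lte(hi, B)
})

test_that("rates follow phi_max * sigmoid on both backends", {
  expect_equal(firing_rate(0, p_default), 0.1)
  expect_equal(firing_rate(2, p_default), 0.2 * plogis(2))
  expect_equal(firing_rate(2, p_default), 0.176159, tolerance = 1e-5)
  expect_equal(firing_rate(1e3, p_default), 0.2)
  hw <- firing_rate(c(-10, 0, 2), p_default, backend = "hw")
  expect_equal(hw, c(0, 0.1, 0.2 * 0.885), tolerance = 1e-3)
  expect_true(all(hw >= 0 & hw <= 0.2))
})

test_that("spike sampling is Bernoulli at the requested rate and
          deterministic under a fixed seed", {
  set.seed(11)
  expect_true(all(sample_spikes(rep(0, 50), p_default) == 0))
  set.seed(11)
  n <- 1e4
  count <- sum(vapply(seq_len(n), function(i) {
    sample_spikes(0.2, p_default)
  }, integer(1)))
  bounds <- qbinom(c(0.005, 0.995), n, 0.2)
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
  set.seed(3); a <- sample_spikes(rep(0.1, 100), p_default)
  set.seed(3); b <- sample_spikes(rep(0.1, 100), p_default)
  expect_identical(a, b)
})

test_that("empirical spike rate of a simulated neuron matches its analytic
          rate", {
  set.seed(8)
  w <- runif(4, -1, 1)
  raster <- matrix(as.integer(runif(4e4) < 0.1), ncol = 4)
  sim <- simulate_hidden_neuron(raster, w, 0.5)
  p_hat <- mean(sim$spikes)
  p_th <- mean(sim$rate)
  se <- sqrt(p_th * (1 - p_th) / length(sim$spikes))
  expect_lt(abs(p_hat - p_th), 3 * se)
})
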