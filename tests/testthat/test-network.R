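test_that("network construction matches the documented synapse counts and
          is reproducible", {
  net <- build_network(8, 10, 4, seed = 1)
  expect_equal(net$n_synapses, 120)
  expect_equal(build_network(8, 10, 8, seed = 1)$n_synapses, 160)
  expect_equal(dim(net$Y), c(10, 4))
  net2 <- build_network(8, 10, 4, seed = 1)
  expect_identical(net$W0, net2$W0)
  expect_identical(net$Y, net2$Y)
  net3 <- build_network(8, 10, 4, seed = 2)
  expect_false(identical(net$W0, net3$W0))
  expect_error(build_network(0, 10, 4))
})

test_that("patterns validate their rate range", {
  expect_error(spike_pattern(c(10, 50)), "20")
  expect_error(spike_pattern(c(50, 500)), "200")
  expect_s3_class(spike_pattern(c(20, 200)), "spike_pattern")
})

test_that("prediction takes the argmax with ties broken to the lowest
          index", {
  expect_equal(predict_class(c(3, 9, 1, 0)), 2)
  expect_equal(predict_class(c(5, 5, 5, 5)), 1)
  expect_equal(predict_class(list(counts = c(0, 0, 7, 7))), 3)
})

test_that("drop noise thins set bits only, at the requested probability", {
  r <- matrix(rep(c(0L, 1L), 50), 10)
  set.seed(1)
  expect_identical(inject_drop_noise(r, 0), r)
  expect_true(all(inject_drop_noise(r, 1) == 0))
  set.seed(2)
  n <- 1e4
  kept <- sum(inject_drop_noise(rep(1L, n), 0.5))
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])
  # zero bits are never touched
  set.seed(3)
  expect_true(all(inject_drop_noise(rep(0L, 100), 0.9) == 0))
})

test_that("trials are deterministic given a seed and compiled/reference
          loops are exchangeable", {
  net <- build_network(8, 10, 4, seed = 3)
  pat <- make_classification_fixture()[[1]]
  for (noise in list(NULL, noise_spec(0.3, "transmission"),
                     noise_spec(0.3, "soma"))) {
    set.seed(42)
    a <- run_trial(net, pat, "train", noise = noise, record = TRUE,
                   use_compiled = TRUE)
    set.seed(42)
    b <- run_trial(net, pat, "train", noise = noise, record = TRUE,
                   use_compiled = FALSE)
    expect_equal(a$counts, b$counts)
    expect_equal(a$net$W0, b$net$W0, tolerance = 1e-12)
    expect_equal(a$net$W1, b$net$W1, tolerance = 1e-12)
    expect_equal(a$trace$V0, b$trace$V0, tolerance = 1e-12)
    expect_true(all(a$trace$in_spikes == b$trace$in_spikes))
  }
  set.seed(9); r1 <- run_trial(net, pat, "test", record = TRUE)
  set.seed(9); r2 <- run_trial(net, pat, "test", record = TRUE)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(r1$trace$out_spikes == r2$trace$out_spikes))
})

test_that("test mode runs the forward phase only and leaves the network
          unchanged", {
  net <- build_network(8, 10, 4, seed = 3)
  pat <- make_classification_fixture()[[2]]
  set.seed(1)
  res <- run_trial(net, pat, "test", readout_ms = 300)
  expect_identical(res$net$W0, net$W0)
  expect_identical(res$net$b1, net$b1)
  expect_equal(res$n_steps, 300)
  expect_length(res$counts, 4)
})

test_that("pattern/network dimension mismatches error", {
  net <- build_network(8, 10, 4, seed = 3)
  expect_error(run_trial(net, spike_pattern(rep(100, 5)), "test"))
})

test_that("the hardware backend runs the full trial loop deterministically", {
  net <- build_network(4, 5, 3, seed = 7, backend = "hw")
  pat <- spike_pattern(rep(c(20, 200), length.out = 4), label = 2)
  addr0 <- net$lut$address
  set.seed(50)
  a <- run_trial(net, pat, "train")
  net$lut$address <- addr0
  set.seed(50)
  b <- run_trial(net, pat, "train")
  expect_identical(a$counts, b$counts)
  expect_identical(a$net$W0, b$net$W0)
  expect_identical(a$net$Y, net$Y)
  # every weight stays on the fixed-point lattice
  expect_true(all(a$net$W0 * 65536 == round(a$net$W0 * 65536)))
})

test_that("the architecture scales to a 784-500-10 configuration", {
  net <- build_network(784, 500, 10, seed = 1)
  expect_equal(net$n_synapses, 784 * 500 + 500 * 10)
  pat <- spike_pattern(runif(784, 20, 200), label = 3)
  set.seed(1)
  res <- run_trial(net, pat, "train")
  expect_length(res$counts, 10)
  expect_false(identical(res$net$W0, net$W0))
})
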