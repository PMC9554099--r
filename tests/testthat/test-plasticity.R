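p_default <- network_params()
sched <- phase_schedule(p_default)

test_that("phase enables are mutually exclusive and the window excludes the
          unstable time", {
  for (ct in c(1, 30, 100, 101, 130, 200)) {
    fl <- phase_flags(sched, ct)
    expect_true(xor(fl$forward_enable, fl$target_enable))
  }
  expect_false(phase_flags(sched, 10)$in_window)
  expect_false(phase_flags(sched, 30)$in_window)
  expect_true(phase_flags(sched, 31)$in_window)
  expect_false(phase_flags(sched, 115)$in_window)
  expect_true(phase_flags(sched, 131)$in_window)
  expect_true(phase_flags(sched, 200)$clear)
  expect_false(phase_flags(sched, 199)$clear)
  expect_error(phase_flags(sched, 201))
})

test_that("exactly 70 samples enter each phase average at the defaults,
          and the unstable time is excluded", {
  acc <- new_accumulators(2, 3, 2)
  for (ct in 1:200) {
    acc <- accumulate_step(acc, ct, x = c(1, 1), V0a = rep(0.5, 3),
                           V0 = rep(1, 3), V1 = c(2, 2), s0 = rep(0.1, 3),
                           sched)
  }
  expect_equal(acc$n_f, 70L)
  expect_equal(acc$n_t, 70L)
  expect_equal(acc$V0a_f / acc$n_f, rep(0.5, 3)) # mean of a constant
  expect_equal(acc$x_f, c(70, 70))               # presynaptic window sum

  # a step inside the unstable window leaves the accumulators untouched
  before <- acc
  acc2 <- accumulate_step(acc, 10, c(9, 9), rep(9, 3), rep(9, 3), c(9, 9),
                          rep(9, 3), sched)
  expect_identical(acc2, before)

  # the delta windowing mode keeps only the last delta_t ms of each phase
  accd <- new_accumulators(2, 3, 2)
  for (ct in 1:200) {
    accd <- accumulate_step(accd, ct, c(1, 1), rep(0.5, 3), rep(1, 3),
                            c(2, 2), rep(0.1, 3), sched,
                            window_mode = "delta")
  }
  expect_equal(accd$n_f, 30L)
  expect_equal(accd$n_t, 30L)
})

test_that("hardware accumulation scales potentials so the finished sum is
          the mean", {
  acc <- new_accumulators(1, 2, 1)
  for (ct in 1:200) {
    acc <- accumulate_step(acc, ct, 1, c(0.5, -0.25), c(1, 1), 2,
                           c(0.1, 0.1), sched, backend = "hw")
  }
  expect_equal(acc$V0a_f, c(0.5, -0.25), tolerance = 70 * 2^-16)
  expect_equal(acc$V1_t, 2, tolerance = 70 * 2^-16)
  expect_equal(acc$x_f, 70, tolerance = 70 * 2^-16)
})

test_that("plateau potential is the sigmoid of the apical mean on either
          backend", {
  expect_equal(plateau_potential(0), 0.5)
  expect_equal(plateau_potential(2), plogis(2))
  expect_equal(plateau_potential(2), 0.8808, tolerance = 1e-4)
  expect_equal(plateau_potential(2, backend = "hw"), 0.885,
               tolerance = 2e-4)
})

test_that("updates vanish at zero error and reproduce hand-computed
          magnitudes under the as-written sign and mean statistics", {
  cfg_printed <- learning_config(update_sign = -1, presyn_stat = "mean")
  # zero error: identical plateau potentials in both phases
  acc <- new_accumulators(2, 3, 2)
  acc$n_f <- acc$n_t <- 70L
  acc$V0a_f <- acc$V0a_t <- rep(0.35, 3) * 70
  acc$V0_f <- rep(0.1, 3) * 70
  acc$x_f <- rep(1, 2) * 70
  acc$V1_f <- acc$V1_t <- rep(0.2, 2) * 70
  acc$s0_f <- rep(0.5, 3) * 70
  W0 <- matrix(0.3, 3, 2); b0 <- rep(0.1, 3)
  h <- hidden_update(W0, b0, acc, cfg_printed, p_default)
  expect_identical(h$W0, W0)
  expect_identical(h$b0, b0)
  o <- output_update(matrix(0.3, 2, 3), rep(0, 2), acc, cfg_printed,
                     p_default)
  expect_equal(o$W1, matrix(0.3, 2, 3))

  # (alpha_t - alpha_f) = 0.1, V0bar_f = 0, xbar_f = 1:
  # dW = -eta0 P0 gb/(gl+gb+ga) * 0.1 * phi_max * sigma'(0) * 1
  acc$V0a_f <- rep(0, 3) * 70
  acc$V0a_t <- rep(qlogis(0.6), 3) * 70
  acc$V0_f <- rep(0, 3)
  h <- hidden_update(W0, b0, acc, cfg_printed, p_default)
  expect_equal(h$W0 - W0, matrix(-3 / 700, 3, 2)) # -0.00428571...
  expect_equal(h$b0 - b0, rep(-3 / 700, 3))

  # doubling xbar doubles dW and leaves db unchanged
  acc2 <- acc; acc2$x_f <- acc$x_f * 2
  h2 <- hidden_update(W0, b0, acc2, cfg_printed, p_default)
  expect_equal(h2$W0 - W0, 2 * (h$W0 - W0))
  expect_equal(h2$b0, h$b0)

  # output layer: (phibar_t - phibar_f) = 0.02 with V1bar_f = 0, s0bar = 1
  acc$V1_f <- rep(0, 2)
  acc$V1_t <- rep(qlogis(0.6), 2) * 70
  acc$s0_f <- rep(1, 3) * 70
  o <- output_update(matrix(0.3, 2, 3), rep(0, 2), acc, cfg_printed,
                     p_default)
  expect_equal(o$W1 - 0.3, matrix(-3 / 700, 2, 3))
  # the default sign applies the same magnitude in the descent direction
  o_desc <- output_update(matrix(0.3, 2, 3), rep(0, 2), acc,
                          learning_config(presyn_stat = "mean"), p_default)
  expect_equal(o_desc$W1 - 0.3, -(o$W1 - 0.3))
})

test_that("the presynaptic-sum convention rescales weight updates by the
          window and leaves bias updates alone", {
  acc <- new_accumulators(1, 2, 1)
  acc$n_f <- acc$n_t <- 70L
  acc$V0a_f <- rep(0, 2); acc$V0a_t <- rep(qlogis(0.6), 2) * 70
  acc$V0_f <- rep(0, 2); acc$x_f <- 0.5 * 70
  acc$V1_f <- 0; acc$V1_t <- 0; acc$s0_f <- rep(0.5, 2) * 70
  W0 <- matrix(0, 2, 1); b0 <- rep(0, 2)
  hs <- hidden_update(W0, b0, acc, learning_config(presyn_stat = "sum"),
                      p_default)
  hm <- hidden_update(W0, b0, acc, learning_config(presyn_stat = "mean"),
                      p_default)
  expect_equal(hs$W0, 70 * hm$W0)
  expect_equal(hs$b0, hm$b0)
})

test_that("end-of-trial application updates feedforward weights once and
          never touches the feedback matrix", {
  net <- tiny_net()
  pat <- spike_pattern(rep(c(20, 200), length.out = net$n_in), label = 1)
  set.seed(21)
  res <- run_trial(net, pat, "train")
  expect_identical(res$net$Y, net$Y)
  expect_false(identical(res$net$W0, net$W0))
  expect_false(identical(res$net$W1, net$W1))
  # re-applying the same accumulators reproduces the same single update
  again <- apply_trial_end(net, res$acc)
  expect_equal(again$W0, res$net$W0)
  expect_equal(again$W1, res$net$W1)
})

test_that("unfinalized accumulators raise a state error", {
  acc <- new_accumulators(1, 2, 1)
  expect_error(hidden_update(matrix(0, 2, 1), rep(0, 2), acc),
               "both phases")
})
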