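test_that("spec validation rejects malformed segment lists", {
  expect_error(pwl_spec(1:3, 1:3, c(2, 1)), "increasing")
  expect_error(pwl_spec(1:3, 1:2, 1:2))
  expect_s3_class(pwl_spec(c(1, 2), c(0, 0), 0), "pwl_spec")
})

test_that("five-segment sigmoid evaluates known points and clips", {
  s5 <- pwl_sigmoid5()
  expect_equal(pwl_eval(s5, 0), 0.5)
  expect_equal(pwl_eval(s5, 2), 0.885)       # 0.0625*2 + 0.76
  expect_equal(pwl_eval(s5, -10), 0)         # clipped below
  expect_equal(pwl_eval(s5, 50), 1)          # clipped above
  # boundary values belong to the lower segment
  expect_equal(pwl_eval(s5, 1.3), 0.25 * 1.3 + 0.5)
})

test_that("six-segment derivative peaks at 0.25 at the origin and stays
          non-negative", {
  d6 <- pwl_dsigmoid6()
  expect_equal(pwl_eval(d6, 0), 0.25)
  V <- seq(-12, 12, by = 0.01)
  y <- pwl_eval(d6, V)
  expect_true(all(y >= 0))
  # the curve's global maximum sits at the origin (the first positive-side
  # intercept overshoots sigma'(0) by 0.01 by construction of the table)
  expect_lt(max(y), 0.2601)
  expect_gte(pwl_eval(d6, 0), max(y) - 0.011)
  s5 <- pwl_eval(pwl_sigmoid5(), V)
  expect_true(all(s5 >= 0 & s5 <= 1))
})

test_that("hardware evaluation equals float evaluation up to quantization", {
  V <- seq(-8, 8, by = 0.037)
  for (spec in list(pwl_sigmoid5(), pwl_dsigmoid6())) {
    f <- pwl_eval(spec, V, backend = "float")
    h <- pwl_eval(spec, V, backend = "hw")
    # every Table-2 slope is a single power of two: one truncating shift
    # of the quantized input plus a quantized intercept
    expect_lt(max(abs(f - h)), 4 * 2^-16 + max(abs(V)) * 2^-16)
  }
})

test_that("approximation errors against the exact functions are at the
          documented levels on the default grid", {
  tab <- pwl_error_table()
  expect_lt(tab$rmse[tab$component == "pwl_sigmoid"], 0.0115)
  expect_gt(tab$r2[tab$component == "pwl_sigmoid"], 0.999)
  expect_lt(tab$rmse[tab$component == "pwl_deriv"], 0.008)
  expect_gt(tab$r2[tab$component == "pwl_deriv"], 0.99)
})

test_that("grid-descent fitting recovers exact and competitive fits", {
  fi <- fit_pwl(function(v) v, 1, fit_range = c(-1, 1))
  expect_equal(attr(fi, "rmse"), 0)
  expect_equal(fi$slopes, 1)
  expect_equal(fi$intercepts, 0)

  fs <- fit_pwl(plogis, 5, fit_range = c(-8, 8), clip = c(0, 1))
  expect_lte(attr(fs, "rmse"), 0.0101) # at least as good as the shipped table

  dsig <- function(v) plogis(v) * (1 - plogis(v))
  fd <- fit_pwl(dsig, 6, fit_range = c(-8, 8), clip = c(0, Inf))
  ship <- sqrt(mean((pwl_eval(pwl_dsigmoid6(), seq(-8, 8, 0.01)) -
                       dsig(seq(-8, 8, 0.01)))^2))
  expect_lt(attr(fd, "rmse"), ship)

  expect_error(fit_pwl(plogis, 5, fit_range = c(1, 1)), "empty")
})
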