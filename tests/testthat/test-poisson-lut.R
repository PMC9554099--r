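test_that("conformity check passes genuine Bernoulli trains and rejects
          degenerate or mismatched ones", {
  set.seed(31)
  passes <- vapply(1:30, function(i) {
    train <- as.integer(runif(1e4) < 0.1)
    chi_square_poisson_check(train, 0.1)$pass
  }, logical(1))
  expect_gt(mean(passes), 0.6) # calibrated near the nominal level

  ones <- chi_square_poisson_check(rep(1L, 1000), 0.1)
  expect_false(ones$pass)
  expect_true(is.finite(ones$p_value))

  zeros <- chi_square_poisson_check(rep(0L, 1000), 0.1)
  expect_false(zeros$pass) # degenerate train fails without error

  set.seed(32)
  wrong <- vapply(1:10, function(i) {
    train <- as.integer(runif(4096) < 0.02)
    chi_square_poisson_check(train, 0.2)$pass
  }, logical(1))
  expect_false(any(wrong)) # power against a tenfold rate mismatch
})

test_that("lookup table holds ten conforming bins with the nominal rates", {
  lut <- poisson_lut_build(seed = 5)
  trains <- poisson_lut_trains(lut)
  expect_equal(dim(trains), c(4096, 10))
  expect_true(all(trains %in% c(0L, 1L)))
  lam <- seq(0.02, 0.2, by = 0.02)
  for (b in 1:10) {
    expect_true(chi_square_poisson_check(trains[, b], lam[b])$pass)
    # spike count within 99% binomial bounds of lambda * length
    bounds <- qbinom(c(0.005, 0.995), 4096, lam[b])
    expect_gte(sum(trains[, b]), bounds[1])
    expect_lte(sum(trains[, b]), bounds[2])
  }
})

test_that("sampling maps rates to 20 Hz segments and advances addresses", {
  lut <- poisson_lut_build(seed = 5)
  set.seed(1)
  poisson_lut_register(lut, 3)
  a0 <- lut$address
  trains <- poisson_lut_trains(lut)
  # rate 200 reads the lambda = 0.2 bin; rate 0 the lowest bin
  bit_hi <- poisson_lut_sample(lut, 200, ids = 1L)
  expect_identical(bit_hi, unname(trains[a0[1], 10]))
  bit_lo <- poisson_lut_sample(lut, 0, ids = 2L)
  expect_identical(bit_lo, unname(trains[a0[2], 1]))
  # successive reads advance by one position
  expect_equal(lut$address[1], a0[1] %% 4096 + 1)
  b2 <- poisson_lut_sample(lut, 200, ids = 1L)
  expect_identical(b2, unname(trains[a0[1] %% 4096 + 1, 10]))
  # boundary rates: 19.9 -> bin 1, 20 -> bin 2, 250 clips to bin 10
  lut$address[] <- 1L
  expect_identical(poisson_lut_sample(lut, 19.9, ids = 1L), unname(trains[1, 1]))
  expect_identical(poisson_lut_sample(lut, 20, ids = 2L), unname(trains[1, 2]))
  expect_identical(poisson_lut_sample(lut, 250, ids = 3L), unname(trains[1, 10]))
})

test_that("address pointers wrap at the train length", {
  lut <- poisson_lut_build(seed = 6, train_length = 128)
  set.seed(2)
  poisson_lut_register(lut, 1)
  lut$address[] <- 128L
  invisible(poisson_lut_sample(lut, 100, ids = 1L))
  expect_equal(lut$address[1], 1L)
})

test_that("identical seeds rebuild identical tables", {
  a <- poisson_lut_trains(poisson_lut_build(seed = 9, train_length = 512))
  b <- poisson_lut_trains(poisson_lut_build(seed = 9, train_length = 512))
  expect_identical(a, b)
})
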