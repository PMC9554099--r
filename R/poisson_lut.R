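# Lookup-table Poisson spike generation. The hardware stores one
# pre-generated binary spike train per 20 Hz frequency segment (ten trains
# covering 0-200 Hz) in shift registers; converting a rate to a spike means
# reading one bit from the train of the rate's segment at the neuron's
# address register and advancing the address.

#' Chi-square conformity check of a binary spike train against Poisson
#'
#' Splits the train into fixed windows, counts spikes per window, and
#' compares the count histogram to the Poisson(`lam * window_ms`)
#' expectation with a chi-square statistic. Count categories are pooled
#' from both ends until every expected count is at least 5.
#'
#' @param train binary (0/1) vector, length >= 100.
#' @param lam per-millisecond spike probability the train should realize.
#' @param window_ms window length (ms) used for counting.
#' @param alpha significance level of the pass/fail verdict.
#' @return list with `statistic`, `df`, `p_value`, `pass`
#'   (`p_value >= alpha`).
#' @export
chi_square_poisson_check <- function(train, lam, window_ms = 20,
                                     alpha = 0.05) {
  stopifnot(length(train) >= 100, all(train %in% c(0, 1)), lam > 0)
  n_win <- length(train) %/% window_ms
  counts <- colSums(matrix(train[seq_len(n_win * window_ms)],
                           nrow = window_ms))
  mu <- lam * window_ms
  kmax <- max(counts, ceiling(mu + 10 * sqrt(mu)))
  probs <- dpois(0:kmax, mu)
  probs[kmax + 1] <- probs[kmax + 1] + stats::ppois(kmax, mu,
                                                    lower.tail = FALSE)
  obs <- tabulate(counts + 1, nbins = kmax + 1)
  expd <- n_win * probs
  # pool sparse categories from both ends toward the center
  lo <- 1; hi <- length(expd)
  while (lo < hi && expd[lo] < 5) {
    expd[lo + 1] <- expd[lo + 1] + expd[lo]
    obs[lo + 1] <- obs[lo + 1] + obs[lo]
    lo <- lo + 1
  }
  while (hi > lo && expd[hi] < 5) {
    expd[hi - 1] <- expd[hi - 1] + expd[hi]
    obs[hi - 1] <- obs[hi - 1] + obs[hi]
    hi <- hi - 1
  }
  obs <- obs[lo:hi]; expd <- expd[lo:hi]
  stat <- sum((obs - expd)^2 / expd)
  df <- max(length(obs) - 1, 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, pass = p >= alpha)
}

#' Build the ten-bin Poisson lookup table
#'
#' Generates ten Bernoulli spike trains with per-ms probabilities
#' 0.02, 0.04, ..., 0.2 (one per 20 Hz segment of the 0-200 Hz range).
#' Each train must pass [chi_square_poisson_check()] at the given
#' significance level; failing trains are regenerated up to `max_retries`
#' times. The returned object is an environment (reference semantics:
#' sampling advances per-neuron address pointers in place).
#'
#' @param seed integer RNG seed for train generation.
#' @param train_length bits stored per train (>= 100). The default 4096 is
#'   long enough that a 200 ms trial never rereads a bit.
#' @param window_ms,alpha arguments of the conformity check.
#' @param max_retries regeneration attempts per bin before erroring.
#' @return An object of class `poisson_lut`.
#' @export
poisson_lut_build <- function(seed, train_length = 4096, window_ms = 20,
                              alpha = 0.05, max_retries = 50) {
  stopifnot(train_length >= 100)
  lut <- new.env(parent = emptyenv())
  lut$lambda <- seq(0.02, 0.2, by = 0.02)
  lut$train_length <- as.integer(train_length)
  lut$bins <- matrix(0L, nrow = train_length, ncol = 10)
  lut$address <- integer(0)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in 1:10) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      train <- as.integer(runif(train_length) < lut$lambda[b])
      chk <- chi_square_poisson_check(train, lut$lambda[b], window_ms, alpha)
      if (chk$pass) { ok <- TRUE; break }
    }
    if (!ok) stop("poisson_lut_build: bin ", b,
                  " failed the conformity check after ", max_retries,
                  " attempts")
    lut$bins[, b] <- train
  }
  class(lut) <- "poisson_lut"
  lut
}

#' Attach per-neuron address pointers to a lookup table
#'
#' Each sampling neuron owns one address register. Pointers start at
#' distinct pseudo-random offsets (drawn from the current RNG stream) so
#' that neurons reading the same frequency bin do not emit identical,
#' fully correlated spike trains.
#'
#' @param lut a [poisson_lut_build()] object.
#' @param n number of neurons to register.
#' @return the lut, invisibly (modified in place).
#' @export
poisson_lut_register <- function(lut, n) {
  lut$address <- sample.int(lut$train_length, n, replace = TRUE)
  invisible(lut)
}

#' Sample one spike bit per neuron from the lookup table
#'
#' Clips each rate into \[0, 200\] Hz, maps it to its 20 Hz frequency
#' segment (`bin = min(9, floor(rate/20))`, zero-based), reads the bit at
#' the neuron's address in that segment's stored train, and advances the
#' address by one with wrap-around.
#'
#' @param lut a registered [poisson_lut_build()] object.
#' @param rates_hz numeric vector of firing rates in Hz.
#' @param ids integer vector of neuron ids (default `seq_along(rates_hz)`).
#' @return integer 0/1 vector of spikes.
#' @export
poisson_lut_sample <- function(lut, rates_hz, ids = seq_along(rates_hz)) {
  stopifnot(length(ids) == length(rates_hz), length(lut$address) > 0,
            max(ids) <= length(lut$address))
  r <- pmin(pmax(rates_hz, 0), 200)
  bin <- pmin(9, floor(r / 20)) + 1L
  addr <- lut$address[ids]
  bits <- lut$bins[cbind(addr, bin)]
  lut$address[ids] <- addr %% lut$train_length + 1L
  bits
}

#' @export
print.poisson_lut <- function(x, ...) {
  cat(sprintf("<poisson_lut: 10 bins x %d bits, %d registered neurons>\n",
              x$train_length, length(x$address)))
  invisible(x)
}

#' Export / import lookup-table trains as a plain raster matrix
#'
#' The stored trains can be round-tripped for bit-exact replay.
#'
#' @param lut a `poisson_lut`.
#' @return integer matrix `train_length x 10`.
#' @export
poisson_lut_trains <- function(lut) {
  m <- lut$bins
  colnames(m) <- sprintf("lambda_%.2f", lut$lambda)
  m
}
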