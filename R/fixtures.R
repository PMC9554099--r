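# Built-in spike-pattern fixtures for the two experiments.

#' The four-pattern classification fixture
#'
#' Four mutually discriminable binary-frequency patterns over 8 channels,
#' every channel at either 20 Hz (low) or 200 Hz (high):
#' pattern 1 = even-index channels high, pattern 2 = its complement,
#' pattern 3 = first half high, pattern 4 = second half high. Labels are
#' 1..4. The patterns are fixed by construction; `seed` is accepted for
#' interface symmetry and ignored.
#'
#' @param seed ignored (the fixture is deterministic).
#' @return list of four labeled [spike_pattern()]s.
#' @export
#' @examples
#' make_classification_fixture()[[1]]$rates # 20 200 20 200 20 200 20 200
make_classification_fixture <- function(seed = NULL) {
  lo <- 20; hi <- 200
  rates <- list(rep(c(lo, hi), 4),
                rep(c(hi, lo), 4),
                c(rep(hi, 4), rep(lo, 4)),
                c(rep(lo, 4), rep(hi, 4)))
  lapply(1:4, function(i) spike_pattern(rates[[i]], label = i))
}

#' A random pattern for the reproduction task
#'
#' Draws 8 channel rates uniformly from \[20, 200\] Hz; the pattern's
#' target rates equal its input rates (the network must reproduce the
#' frequency distribution it receives).
#'
#' @param seed integer seed; identical seeds give identical patterns.
#' @param n_channels number of channels.
#' @return a [spike_pattern()] with `target_rates == rates`.
#' @export
make_reproduction_fixture <- function(seed, n_channels = 8) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- runif(n_channels, 20, 200)
  spike_pattern(r, target_rates = r)
}
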