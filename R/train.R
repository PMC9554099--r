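# Training harnesses for the two experiments: frequency-pattern
# classification and pattern reproduction, with optional drop noise.

#' Train a network on a set of spike patterns
#'
#' Iterates the patterns in a fixed cyclic order (optionally shuffled per
#' epoch), running one two-phase training trial per pattern per epoch.
#' Optionally evaluates the classification accuracy every `eval_every`
#' epochs on forward-only readouts.
#'
#' @param net an [build_network()] network.
#' @param patterns list of [spike_pattern()]s.
#' @param epochs number of training epochs (>= 0).
#' @param seed integer seed for the trial RNG; the run is reproducible
#'   from `(net$seed, seed)` alone.
#' @param shuffle shuffle pattern order each epoch.
#' @param eval_every evaluate accuracy every this many epochs (0 = never).
#' @param readout_ms readout window of evaluation trials (ms).
#' @param noise optional [noise_spec()].
#' @param noise_during which trials the noise applies to: `"test"`
#'   (default; the trained network is probed through a lossy channel),
#'   `"train"` or `"both"`.
#' @return list with `net` (trained), and `log` (data.frame of `epoch`,
#'   `accuracy` for evaluated epochs; zero rows if `eval_every = 0`).
#' @export
train_network <- function(net, patterns, epochs, seed = 1, shuffle = FALSE,
                          eval_every = 0, readout_ms = 1000, noise = NULL,
                          noise_during = c("test", "train", "both")) {
  noise_during <- match.arg(noise_during)
  stopifnot(epochs >= 0)
  train_noise <- if (noise_during %in% c("train", "both")) noise
  test_noise <- if (noise_during %in% c("test", "both")) noise
  set.seed(seed)
  log <- data.frame(epoch = integer(0), accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample(seq_along(patterns)) else seq_along(patterns)
    for (i in ord) {
      net <- run_trial(net, patterns[[i]], "train", noise = train_noise)$net
    }
    if (eval_every > 0 && ep %% eval_every == 0) {
      acc <- classification_accuracy(net, patterns, readout_ms, test_noise)
      log <- rbind(log, data.frame(epoch = ep, accuracy = acc))
    }
  }
  list(net = net, log = log)
}

#' Classification accuracy over a pattern set
#'
#' Runs one forward-only test trial per labeled pattern and scores the
#' argmax-of-spike-counts prediction.
#'
#' @param net a trained network.
#' @param patterns list of labeled [spike_pattern()]s.
#' @param readout_ms readout window (ms).
#' @param noise optional [noise_spec()] applied to the test trials.
#' @return fraction of patterns classified correctly.
#' @export
classification_accuracy <- function(net, patterns, readout_ms = 1000,
                                    noise = NULL) {
  preds <- vapply(patterns, function(p) {
    predict_class(run_trial(net, p, "test", noise = noise,
                            readout_ms = readout_ms))
  }, numeric(1))
  labels <- vapply(patterns, function(p) p$label, numeric(1))
  mean(preds == labels)
}

#' Evaluate pattern reproduction
#'
#' Runs an unnudged forward simulation for `readout_ms` milliseconds,
#' estimates each output neuron's rate as `count / readout_ms * 1000` Hz,
#' and scores the estimates against the pattern's target rates with RMSE,
#' MAE and R-square.
#'
#' @param net a trained network with `n_out == length(target rates)`.
#' @param pattern a [spike_pattern()] carrying `target_rates`.
#' @param readout_ms readout window (ms).
#' @param noise optional [noise_spec()].
#' @return list with `rates_hz` (estimated output rates), `rmse`, `mae`,
#'   `r2`.
#' @export
evaluate_reproduction <- function(net, pattern, readout_ms = 1000,
                                  noise = NULL) {
  target <- pattern$target_rates
  stopifnot(!is.null(target), length(target) == net$n_out)
  res <- run_trial(net, pattern, "test", noise = noise,
                   readout_ms = readout_ms)
  rates <- res$counts / readout_ms * 1000
  list(rates_hz = rates, rmse = rmse(target, rates),
       mae = mae(target, rates), r2 = r_squared(target, rates))
}

#' Classification experiment
#'
#' Builds an `8 x 10 x 4` network, trains it for `epochs` epochs on the
#' four binary-frequency fixture patterns (one two-phase trial per pattern
#' per epoch) and reports the final test accuracy.
#'
#' @param seed integer seed (controls initialization and all trial RNG).
#' @param epochs training epochs.
#' @param backend `"float"` or `"hw"`.
#' @param readout_ms test readout window (ms).
#' @param eval_every accuracy-log interval passed to [train_network()].
#' @return list with `accuracy`, `net`, `log`.
#' @export
run_classification_experiment <- function(seed, epochs = 500,
                                          backend = "float",
                                          readout_ms = 1000,
                                          eval_every = 0) {
  patterns <- make_classification_fixture()
  net <- build_network(8, 10, 4, backend = backend, seed = seed)
  fit <- train_network(net, patterns, epochs, seed = seed + 1000,
                       eval_every = eval_every, readout_ms = readout_ms)
  set.seed(seed + 2000)
  acc <- classification_accuracy(fit$net, patterns, readout_ms)
  list(accuracy = acc, net = fit$net, log = fit$log)
}

#' Pattern-reproduction experiment
#'
#' Builds an `8 x 10 x 8` network, trains it for `epochs` epochs to
#' reproduce a random 8-channel frequency pattern under graded nudging,
#' and scores the reproduced output rates against the input rates. Drop
#' noise, when requested, thins the input spike trains of the test
#' readout: the trained network is probed through a lossy channel.
#'
#' @param seed integer seed.
#' @param epochs training epochs.
#' @param drop_prob input spike drop probability (0 = no noise).
#' @param backend `"float"` or `"hw"`.
#' @param readout_ms test readout window (ms). The default 4000 keeps the
#'   Poisson rate-estimation error of the readout itself (about
#'   `sqrt(r / readout_s)` Hz per channel) below the network's own
#'   reproduction error; see the vignette.
#' @param noise_during which trials the noise applies to (see
#'   [train_network()]).
#' @return list with `mae`, `r2`, `rates_hz`, `target_hz`, `net`.
#' @export
run_reproduction_experiment <- function(seed, epochs = 300, drop_prob = 0,
                                        backend = "float",
                                        readout_ms = 4000,
                                        noise_during = "test") {
  pattern <- make_reproduction_fixture(seed)
  net <- build_network(8, 10, 8, backend = backend, seed = seed)
  noise <- if (drop_prob > 0) noise_spec(drop_prob, "transmission")
  train_noise <- if (!is.null(noise) && noise_during %in% c("train", "both"))
    noise
  fit <- train_network(net, list(pattern), epochs, seed = seed + 1000,
                       noise = train_noise, noise_during = "train")
  set.seed(seed + 2000)
  test_noise <- if (!is.null(noise) && noise_during %in% c("test", "both"))
    noise
  ev <- evaluate_reproduction(fit$net, pattern, readout_ms, test_noise)
  list(mae = ev$mae, r2 = ev$r2, rates_hz = ev$rates_hz,
       target_hz = pattern$target_rates, net = fit$net)
}
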