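# Assembly of the three-layer network and the 200 ms two-phase trial loop.

#' Frequency-coded spike pattern
#'
#' @param rates per-channel target firing rates in Hz (each in
#'   \[20, 200\]).
#' @param label class index (1-based) for classification, or `NA`.
#' @param target_rates per-output target rates (Hz) for the
#'   pattern-reproduction task, or `NULL`.
#' @return a `spike_pattern` object.
#' @export
spike_pattern <- function(rates, label = NA_integer_, target_rates = NULL) {
  if (any(rates < 20 | rates > 200)) {
    stop("spike_pattern: channel rates must lie within [20, 200] Hz")
  }
  structure(list(rates = as.numeric(rates), label = label,
                 target_rates = target_rates),
            class = "spike_pattern")
}

#' Drop-noise specification
#'
#' Spikes are dropped independently with a constant probability at one of
#' three points: `"transmission"` (the default) thins every spike train
#' travelling between layers — the input rasters entering the hidden
#' basal dendrites and the hidden soma outputs entering the output basal
#' dendrites — modelling lossy inter-layer spike links while each output
#' neuron's own spike counter still sees its soma directly. `"input"`
#' thins only the input rasters; `"soma"` thins the outputs of every
#' soma, including the output layer's own spikes (and therefore the
#' readout counts).
#'
#' @param drop_prob probability in \[0, 1\] that any given spike is lost.
#' @param where `"transmission"`, `"input"` or `"soma"`.
#' @return a `noise_spec` object.
#' @export
noise_spec <- function(drop_prob,
                       where = c("transmission", "input", "soma")) {
  stopifnot(drop_prob >= 0, drop_prob <= 1)
  structure(list(drop_prob = drop_prob, where = match.arg(where)),
            class = "noise_spec")
}

#' Drop spikes from a binary raster
#'
#' Each 1-bit is independently set to 0 with probability `drop_prob`;
#' 0-bits are untouched. Draws come from R's current RNG stream (one draw
#' per raster entry, so the stream advance does not depend on the data).
#'
#' @param raster binary vector or matrix.
#' @param drop_prob drop probability.
#' @return the thinned raster, same shape.
#' @export
inject_drop_noise <- function(raster, drop_prob) {
  stopifnot(all(raster %in% c(0, 1)))
  if (drop_prob <= 0) return(raster)
  u <- runif(length(raster))
  out <- raster
  out[raster == 1 & u < drop_prob] <- 0L
  out
}

#' Build a three-layer MLIF spiking network
#'
#' Initializes `W0, W1 ~ U(-w_scale, w_scale)`, output biases at 0, hidden
#' biases at `b0_init`, and the fixed feedback weights
#' `Y ~ U(-y_scale, y_scale)` from the given seed. The default scales put
#' the network in its operating regime given the ~0.1-scale filtered spike
#' traces: dendritic potentials of order one on the sigmoid's sensitive
#' range, a positive hidden bias so the hidden layer rests in an active
#' (spike-emitting) state, and feedback strong enough that the nudged
#' output layer measurably moves the apical plateau potentials (see the
#' vignette for the scaling analysis). On the hardware backend the weights
#' are quantized to 24-bit fixed point and a Poisson lookup table is built
#' and registered for every spiking unit.
#'
#' @param n_in,n_hidden,n_out layer sizes (>= 1).
#' @param params a [network_params()].
#' @param config a [learning_config()].
#' @param backend `"float"` or `"hw"`.
#' @param seed integer seed; identical seeds give identical networks.
#' @param w_scale half-width of the uniform feedforward-weight
#'   initialization.
#' @param y_scale half-width of the uniform feedback-weight
#'   initialization.
#' @param b0_init initial hidden bias.
#' @return an object of class `snn_network`.
#' @export
#' @examples
#' net <- build_network(8, 10, 4, seed = 1)
#' net$n_synapses # 120
build_network <- function(n_in, n_hidden, n_out,
                          params = network_params(),
                          config = learning_config(),
                          backend = c("float", "hw"), seed = 1,
                          w_scale = 1, y_scale = 4, b0_init = 2) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  backend <- match.arg(backend)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  q <- if (backend == "hw") fx_quantize else identity
  net <- structure(list(
    n_in = n_in, n_hidden = n_hidden, n_out = n_out,
    W0 = q(matrix(runif(n_hidden * n_in, -w_scale, w_scale), n_hidden, n_in)),
    b0 = q(rep(b0_init, n_hidden)),
    W1 = q(matrix(runif(n_out * n_hidden, -w_scale, w_scale), n_out, n_hidden)),
    b1 = numeric(n_out),
    Y = q(matrix(runif(n_hidden * n_out, -y_scale, y_scale), n_hidden, n_out)),
    params = params, config = config, backend = backend, seed = seed,
    n_synapses = n_in * n_hidden + n_hidden * n_out,
    lut = NULL), class = "snn_network")
  if (backend == "hw") {
    net$lut <- poisson_lut_build(seed = seed + 1)
    poisson_lut_register(net$lut, n_in + n_hidden + n_out)
  }
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network %d-%d-%d, %d synapses, backend=%s>\n",
              x$n_in, x$n_hidden, x$n_out, x$n_synapses, x$backend))
  invisible(x)
}

# Teaching conductances encoding a pattern's target. Classification: the
# label's neuron is excited (g_E=1, g_I=0), all others inhibited (0, 1).
# Reproduction: graded nudging with g_E chosen so that the nudged somatic
# voltage settles at logit(r / rate_max), the voltage whose converged
# forward rate equals the target rate r (see the vignette for the fixed
# point derivation); g_I = 1 - g_E.
teaching_conductances <- function(pattern, n_out, params) {
  if (!is.null(pattern$target_rates)) {
    r <- pattern$target_rates
    stopifnot(length(r) == n_out)
    rate_max <- params$phi_max * 1000
    ratio <- pmin(pmax(r / rate_max, 1e-4), 1 - 1e-4)
    g_E <- (qlogis(ratio) - params$E_I) / (params$E_E - params$E_I)
    g_E <- pmin(pmax(g_E, 0), 1)
    list(g_E = g_E, g_I = 1 - g_E)
  } else if (!is.na(pattern$label)) {
    stopifnot(pattern$label >= 1, pattern$label <= n_out)
    g_E <- as.numeric(seq_len(n_out) == pattern$label)
    list(g_E = g_E, g_I = 1 - g_E)
  } else {
    stop("pattern carries neither a label nor target rates")
  }
}

#' Run one trial of the two-phase schedule
#'
#' In `"train"` mode the network is simulated for one full
#' forward-plus-target trial (200 ms at the defaults): input spikes are
#' Poisson-encoded from the pattern's rates, filtered, and driven through
#' hidden and output MLIF layers, with apical feedback from output spikes
#' through the fixed `Y`; the teaching current nudges the output somata
#' during the target phase, the phase averages are accumulated outside the
#' unstable time, and the plasticity update is applied once at the trial's
#' end. In `"test"` mode only an unnudged forward simulation of
#' `readout_ms` steps is run and output spikes are counted.
#'
#' The float backend runs a compiled loop by default; `use_compiled =
#' FALSE` selects the plain R reference loop, which produces identical
#' results for identical RNG states.
#'
#' @param net an [build_network()] network.
#' @param pattern a [spike_pattern()] with `length(rates) == n_in`.
#' @param mode `"train"` or `"test"`.
#' @param noise optional [noise_spec()] applied within this trial.
#' @param readout_ms test-mode duration (ms).
#' @param record if `TRUE`, also return voltage traces and spike rasters.
#' @param use_compiled use the compiled float-backend loop.
#' @return list with `net` (updated in train mode), `counts` (per-output
#'   spike counts), `n_steps`, and optionally `trace` (a list of matrices).
#' @export
run_trial <- function(net, pattern, mode = c("train", "test"), noise = NULL,
                      readout_ms = 1000, record = FALSE,
                      use_compiled = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(pattern, "spike_pattern"),
            length(pattern$rates) == net$n_in)
  sched <- phase_schedule(net$params)
  train <- mode == "train"
  n_steps <- if (train) sched$total else readout_ms
  teach <- if (train) teaching_conductances(pattern, net$n_out, net$params)
           else list(g_E = numeric(net$n_out), g_I = numeric(net$n_out))
  drop_prob <- if (is.null(noise)) 0 else noise$drop_prob
  noise_where <- if (is.null(noise)) 0L else
    match(noise$where, c("input", "soma", "transmission"))

  if (net$backend == "float" && use_compiled) {
    res <- run_trial_core(net$W0, net$b0, net$W1, net$b1, net$Y,
                          pattern$rates / 1000 * net$params$dt,
                          teach$g_E, teach$g_I,
                          unclass(net$params), n_steps, train,
                          sched$t_forward, sched$delta_t,
                          net$config$plateau_window_mode == "delta",
                          drop_prob, noise_where, record)
    acc <- if (train) {
      a <- new_accumulators(net$n_in, net$n_hidden, net$n_out)
      a[names(res$acc)] <- res$acc
      a
    }
  } else {
    res <- run_trial_r(net, pattern, teach, n_steps, train, sched,
                       drop_prob, noise_where, record)
    acc <- res$acc
  }
  if (train) net <- apply_trial_end(net, acc)
  out <- list(net = net, counts = as.numeric(res$counts), n_steps = n_steps)
  if (record) out$trace <- res$trace
  if (train) out$acc <- acc
  out
}

# Plain-R trial loop: the executable reference for the compiled core, and
# the only loop for the hardware backend. Consumes RNG draws in a fixed
# order (input uniforms, [input noise], hidden uniforms, output uniforms,
# [soma noise]) so that compiled and interpreted paths are exchangeable.
run_trial_r <- function(net, pattern, teach, n_steps, train, sched,
                        drop_prob, noise_where, record) {
  p <- net$params
  hw <- net$backend == "hw"
  be <- net$backend
  q <- if (hw) fx_quantize else identity
  in_bank <- filter_bank(net$n_in, p, backend = be)
  hid_bank <- filter_bank(net$n_hidden, p, backend = be)
  out_bank <- filter_bank(net$n_out, p, backend = be)
  V0 <- rep(p$V_res, net$n_hidden)
  V1 <- rep(p$V_res, net$n_out)
  counts <- numeric(net$n_out)
  acc <- new_accumulators(net$n_in, net$n_hidden, net$n_out)
  p_in <- pattern$rates / 1000 * p$dt
  ids_in <- seq_len(net$n_in)
  ids_hid <- net$n_in + seq_len(net$n_hidden)
  ids_out <- net$n_in + net$n_hidden + seq_len(net$n_out)
  if (record) {
    trace <- list(V0 = matrix(0, n_steps, net$n_hidden),
                  V1 = matrix(0, n_steps, net$n_out),
                  in_spikes = matrix(0L, n_steps, net$n_in),
                  out_spikes = matrix(0L, n_steps, net$n_out))
  }
  for (tt in seq_len(n_steps)) {
    in_spk <- if (hw) {
      poisson_lut_sample(net$lut, pattern$rates, ids_in)
    } else {
      as.integer(runif(net$n_in) < p_in)
    }
    if (noise_where %in% c(1L, 3L) && drop_prob > 0) {
      in_spk <- inject_drop_noise(in_spk, drop_prob)
    }
    in_bank <- filter_update(in_bank, in_spk)
    x <- in_bank$s
    V0b <- q(basal_potential(net$W0, x, net$b0))
    V0a <- q(apical_potential(net$Y, out_bank$s))
    V0 <- q(soma_step_hidden(V0, V0b, V0a, p))
    phi0 <- firing_rate(V0, p, be)
    hid_spk <- sample_spikes(phi0, p, be, net$lut, ids_hid)
    if (noise_where %in% c(2L, 3L) && drop_prob > 0) {
      hid_spk <- inject_drop_noise(hid_spk, drop_prob)
    }
    hid_bank <- filter_update(hid_bank, hid_spk)
    s0 <- hid_bank$s
    V1b <- q(basal_potential(net$W1, s0, net$b1))
    phase_target <- train && tt > sched$t_forward
    I <- if (phase_target) {
      q(teaching_current(V1, teach$g_E, teach$g_I, p))
    } else numeric(net$n_out)
    V1 <- q(soma_step_output(V1, V1b, I, p))
    phi1 <- firing_rate(V1, p, be)
    out_spk <- sample_spikes(phi1, p, be, net$lut, ids_out)
    if (noise_where == 2L && drop_prob > 0) {
      out_spk <- inject_drop_noise(out_spk, drop_prob)
    }
    out_bank <- filter_update(out_bank, out_spk)
    counts <- counts + out_spk
    if (train) {
      acc <- accumulate_step(acc, tt, x, V0a, V0, V1, s0, sched, be,
                             net$config$plateau_window_mode)
    }
    if (record) {
      trace$V0[tt, ] <- V0; trace$V1[tt, ] <- V1
      trace$in_spikes[tt, ] <- in_spk; trace$out_spikes[tt, ] <- out_spk
    }
  }
  out <- list(counts = counts, acc = acc)
  if (record) out$trace <- trace
  out
}

#' Predicted class of a trial
#'
#' The output neuron with the most spikes is the prediction; ties break
#' toward the lowest index.
#'
#' @param counts per-output spike counts (or a [run_trial()] result).
#' @return 1-based class index.
#' @export
#' @examples
#' predict_class(c(3, 9, 1, 0)) # 2
predict_class <- function(counts) {
  if (is.list(counts)) counts <- counts$counts
  which.max(counts)
}
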