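# MLIF neuron dynamics: double-exponential synaptic filtering, dendritic
# potentials, forward-Euler somatic updates, sigmoidal rate conversion and
# Poisson spike sampling.

#' Double-exponential synaptic kernel
#'
#' `K(t) = (exp(-t/tau_l) - exp(-t/tau_s)) / (tau_l - tau_s)` for `t > 0`,
#' zero otherwise.
#'
#' @param t time since the presynaptic spike (ms); vectorized.
#' @param params a [network_params()].
#' @return numeric vector of kernel values.
#' @export
#' @examples
#' kernel_value(3, network_params()) # (exp(-0.3) - exp(-1)) / 7
kernel_value <- function(t, params = network_params()) {
  ifelse(t > 0,
         (exp(-t / params$tau_l) - exp(-t / params$tau_s)) /
           (params$tau_l - params$tau_s),
         0)
}

#' Kernel taps of the truncated 10 ms filter window
#'
#' The digital filter holds the kernel at integer lags 1..`n_taps` ms in
#' shift registers; a spike contributes from the step after it occurs
#' (a 1-step register separates soma output and filter input). Both
#' backends truncate the kernel to this window so their traces are
#' comparable; the neglected tail of the slow exponential is below
#' `exp(-1)` of its peak at the default constants.
#'
#' @param params a [network_params()].
#' @param n_taps window length in taps (ms).
#' @param backend `"float"` or `"hw"` (taps quantized to fixed point).
#' @return numeric vector `K(1), ..., K(n_taps)`.
#' @export
kernel_taps <- function(params = network_params(), n_taps = 10,
                        backend = c("float", "hw")) {
  backend <- match.arg(backend)
  taps <- kernel_value(seq_len(n_taps), params)
  if (backend == "hw") taps <- fx_quantize(taps)
  taps
}

#' Create a synaptic filter bank
#'
#' Holds, per channel, the shift register of the last `n_taps` spike bits
#' and the current filtered value `s(t)`.
#'
#' @param n_channels number of channels.
#' @param params a [network_params()].
#' @param n_taps window length (ms).
#' @param backend `"float"` or `"hw"`.
#' @return a `filter_bank` list with fields `taps`, `hist`, `s`, `backend`.
#' @export
filter_bank <- function(n_channels, params = network_params(), n_taps = 10,
                        backend = c("float", "hw")) {
  backend <- match.arg(backend)
  structure(list(taps = kernel_taps(params, n_taps, backend),
                 hist = matrix(0, nrow = n_taps, ncol = n_channels),
                 s = numeric(n_channels),
                 backend = backend),
            class = "filter_bank")
}

#' Advance a filter bank by one millisecond
#'
#' Computes `s(t) = sum_{tau=1..n_taps} K(tau) * spike(t - tau)` from the
#' stored history, then pushes the current step's spikes into the history
#' (they contribute from the next step onward).
#'
#' @param bank a [filter_bank()].
#' @param spikes 0/1 vector, one bit per channel.
#' @return the updated bank; `bank$s` is the filtered value at the current
#'   step.
#' @export
filter_update <- function(bank, spikes) {
  if (length(spikes) != ncol(bank$hist)) {
    stop("filter_update: expected ", ncol(bank$hist), " spike bits, got ",
         length(spikes))
  }
  s <- colSums(bank$hist * bank$taps)
  if (bank$backend == "hw") s <- fx_quantize(s)
  bank$s <- s
  n <- nrow(bank$hist)
  bank$hist <- rbind(spikes, bank$hist[-n, , drop = FALSE], deparse.level = 0)
  bank
}

#' Basal dendritic potential
#'
#' Affine map of the filtered presynaptic activity: `W x + b`.
#'
#' @param W weight matrix (postsynaptic x presynaptic).
#' @param filtered_input numeric vector of filtered spike trains.
#' @param b bias vector (one per postsynaptic neuron).
#' @return numeric vector of dendritic potentials.
#' @export
basal_potential <- function(W, filtered_input, b) {
  if (ncol(W) != length(filtered_input) || nrow(W) != length(b)) {
    stop("basal_potential: dimension mismatch")
  }
  as.vector(W %*% filtered_input + b)
}

#' Apical dendritic potential
#'
#' Linear feedback map `Y s1` of the filtered output-layer spike trains;
#' the apical compartment has no bias.
#'
#' @param Y feedback weight matrix (hidden x output), fixed during training.
#' @param filtered_feedback filtered output-layer spike trains.
#' @return numeric vector of apical potentials.
#' @export
apical_potential <- function(Y, filtered_feedback) {
  if (ncol(Y) != length(filtered_feedback)) {
    stop("apical_potential: dimension mismatch")
  }
  as.vector(Y %*% filtered_feedback)
}

#' One Euler step of the hidden-layer soma
#'
#' `V0 <- V0 + (g_l (V_res - V0) + g_b (V0b - V0) + g_a (V0a - V0)) / C_m`,
#' with the 1 ms step absorbed in the conductances. The apical term is
#' present as written; at the default `g_a = 0` the apical compartment
#' influences learning only.
#'
#' @param V0 somatic voltages.
#' @param V0b,V0a basal and apical dendritic potentials.
#' @param params a [network_params()].
#' @return updated somatic voltages.
#' @export
soma_step_hidden <- function(V0, V0b, V0a, params = network_params()) {
  V0 + (params$g_l * (params$V_res - V0) + params$g_b * (V0b - V0) +
          params$g_a * (V0a - V0)) / params$C_m
}

#' Teaching current of an output neuron
#'
#' `I = g_E (E_E - V1) + g_I (E_I - V1)`. Both conductances are zero in
#' the forward phase, so the current vanishes there.
#'
#' @param V1 output somatic voltages.
#' @param g_E,g_I per-neuron nudging conductances.
#' @param params a [network_params()].
#' @return numeric vector of nudging currents.
#' @export
teaching_current <- function(V1, g_E, g_I, params = network_params()) {
  g_E * (params$E_E - V1) + g_I * (params$E_I - V1)
}

#' One Euler step of the output-layer soma
#'
#' `V1 <- V1 + (g_l (V_res - V1) + g_d (V1b - V1) + I) / C_m`. The output
#' neuron has no apical compartment.
#'
#' @param V1 somatic voltages.
#' @param V1b basal dendritic potentials.
#' @param I teaching currents (see [teaching_current()]).
#' @param params a [network_params()].
#' @return updated somatic voltages.
#' @export
soma_step_output <- function(V1, V1b, I, params = network_params()) {
  V1 + (params$g_l * (params$V_res - V1) + params$g_d * (V1b - V1) + I) /
    params$C_m
}

#' Somatic voltage to firing rate
#'
#' `phi = phi_max * sigmoid(V)`. The float backend uses the exact sigmoid;
#' the hardware backend evaluates the five-segment PWL sigmoid in fixed
#' point and multiplies by `phi_max` with a shift-add constant multiplier.
#'
#' @param V somatic voltages.
#' @param params a [network_params()].
#' @param backend `"float"` or `"hw"`.
#' @return firing rates in spikes/ms, within `[0, phi_max]`.
#' @export
#' @examples
#' firing_rate(0, network_params()) # 0.1 spikes/ms = 100 Hz
firing_rate <- function(V, params = network_params(),
                        backend = c("float", "hw")) {
  backend <- match.arg(backend)
  if (backend == "float") {
    params$phi_max * plogis(V)
  } else {
    fx_const_mul(fx_quantize(params$phi_max),
                 pwl_eval(pwl_sigmoid5(), V, backend = "hw"))
  }
}

#' Sample spikes from firing rates
#'
#' The float backend draws independent Bernoulli(`rate * dt`) bits from
#' R's RNG; the hardware backend reads bits from the Poisson lookup table
#' with the rate expressed in Hz.
#'
#' @param rates firing rates in spikes/ms.
#' @param params a [network_params()].
#' @param backend `"float"` or `"hw"`.
#' @param lut a registered [poisson_lut_build()] (hardware backend).
#' @param ids neuron ids within the lut's address registers.
#' @return integer 0/1 vector.
#' @export
sample_spikes <- function(rates, params = network_params(),
                          backend = c("float", "hw"), lut = NULL,
                          ids = seq_along(rates)) {
  backend <- match.arg(backend)
  if (backend == "float") {
    as.integer(runif(length(rates)) < rates * params$dt)
  } else {
    if (is.null(lut)) stop("sample_spikes: hardware backend needs a lut")
    poisson_lut_sample(lut, rates * 1000, ids)
  }
}

#' Simulate a single hidden MLIF neuron on a fixed input raster
#'
#' Drives one three-compartment neuron with a given binary input raster
#' (and optionally a feedback raster into the apical compartment) and
#' records the somatic voltage, rate and spike trace. Used to compare the
#' fixed-point hardware arithmetic against the floating-point reference on
#' identical inputs.
#'
#' @param input_raster binary matrix, time x channels.
#' @param w weight vector (one per input channel).
#' @param b bias (scalar).
#' @param params a [network_params()].
#' @param backend `"float"` or `"hw"`.
#' @param Y feedback weight vector, or `NULL` for no apical drive.
#' @param feedback_raster binary matrix time x feedback channels.
#' @param lut optional prebuilt lookup table for the hardware backend
#'   (built from `seed` 1 if omitted); spike sampling draws do not affect
#'   the voltage trace.
#' @return list with numeric vectors `V`, `rate` and integer `spikes`,
#'   one entry per time step.
#' @export
simulate_hidden_neuron <- function(input_raster, w, b,
                                   params = network_params(),
                                   backend = c("float", "hw"),
                                   Y = NULL, feedback_raster = NULL,
                                   lut = NULL) {
  backend <- match.arg(backend)
  stopifnot(ncol(input_raster) == length(w))
  n_steps <- nrow(input_raster)
  q <- if (backend == "hw") fx_quantize else identity
  if (backend == "hw" && is.null(lut)) {
    lut <- poisson_lut_build(seed = 1)
    poisson_lut_register(lut, 1)
  }
  bank <- filter_bank(length(w), params, backend = backend)
  fb_bank <- if (!is.null(Y)) {
    filter_bank(length(Y), params, backend = backend)
  }
  w <- q(w); b <- q(b); if (!is.null(Y)) Y <- q(Y)
  V <- numeric(n_steps); rate <- numeric(n_steps)
  spikes <- integer(n_steps)
  V0 <- params$V_res
  for (t in seq_len(n_steps)) {
    bank <- filter_update(bank, input_raster[t, ])
    x <- bank$s
    V0b <- if (backend == "hw") {
      fx_quantize(sum(fx_quantize(w * x)) + b)
    } else {
      sum(w * x) + b
    }
    V0a <- 0
    if (!is.null(Y)) {
      fb_bank <- filter_update(fb_bank, feedback_raster[t, ])
      V0a <- if (backend == "hw") {
        fx_quantize(sum(fx_quantize(Y * fb_bank$s)))
      } else {
        sum(Y * fb_bank$s)
      }
    }
    V0 <- q(soma_step_hidden(V0, V0b, V0a, params))
    V[t] <- V0
    rate[t] <- firing_rate(V0, params, backend)
    spikes[t] <- sample_spikes(rate[t], params, backend, lut, ids = 1L)
  }
  list(V = V, rate = rate, spikes = spikes)
}
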