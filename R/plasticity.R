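# Two-phase plateau-potential plasticity. During a 200 ms trial the
# controller runs a 100 ms forward phase (no teaching) and a 100 ms target
# phase (output somata nudged toward the label). Each phase's apical
# potentials, somatic voltages and presynaptic activities are averaged over
# the phase excluding the initial unstable time; weights and biases are
# updated once, at the end of the target phase, from the difference of the
# two phases' plateau potentials (hidden layer) and mean firing rates
# (output layer). The feedback weights Y are never modified.

#' Two-phase trial schedule
#'
#' The controller counts 1..`t_forward + t_target` (default 200) and wraps
#' with a clear pulse; the ping-pong switch flips to the target side when
#' the counter passes `t_forward`. Exactly one phase enable is active at
#' any step.
#'
#' @param params a [network_params()].
#' @return a `phase_schedule` list with fields `t_forward`, `t_target`,
#'   `delta_t`, `total`.
#' @export
phase_schedule <- function(params = network_params()) {
  structure(list(t_forward = params$t_forward, t_target = params$t_target,
                 delta_t = params$delta_t,
                 total = params$t_forward + params$t_target),
            class = "phase_schedule")
}

#' Phase flags at a counter value
#'
#' @param schedule a [phase_schedule()].
#' @param counter step within the trial, 1..total.
#' @return list with logical `forward_enable`, `target_enable` (mutually
#'   exclusive), `in_window` (past the unstable time of the active phase)
#'   and `clear` (true at the trial's final step).
#' @export
phase_flags <- function(schedule, counter) {
  stopifnot(counter >= 1, counter <= schedule$total)
  fwd <- counter <= schedule$t_forward
  within <- if (fwd) counter else counter - schedule$t_forward
  list(forward_enable = fwd, target_enable = !fwd,
       in_window = within > schedule$delta_t,
       clear = counter == schedule$total)
}

#' Fresh plasticity accumulators
#'
#' Per-phase running sums of the quantities entering the end-of-trial
#' update: apical potentials (both phases), hidden somatic voltages,
#' filtered inputs and hidden activities (forward phase), and output
#' somatic voltages (both phases), plus per-phase sample counts.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @return a `plasticity_acc` list of zeroed sums.
#' @export
new_accumulators <- function(n_in, n_hidden, n_out) {
  structure(list(n_f = 0L, n_t = 0L,
                 V0a_f = numeric(n_hidden), V0a_t = numeric(n_hidden),
                 V0_f = numeric(n_hidden),
                 x_f = numeric(n_in),
                 V1_f = numeric(n_out), V1_t = numeric(n_out),
                 s0_f = numeric(n_hidden)),
            class = "plasticity_acc")
}

#' Accumulate one step's state into the phase averages
#'
#' Adds the current apical potentials, somatic voltages, filtered input and
#' hidden activity into the active phase's sums, but only once the
#' within-phase time exceeds the unstable time. On the hardware backend
#' each added term is first scaled by the fixed-point constant
#' `1/window` (window = phase duration minus unstable time, 70 at the
#' defaults), so the finished sum is already the mean.
#'
#' @param acc a [new_accumulators()] object.
#' @param counter trial step.
#' @param x,V0a,V0,V1,s0 current state vectors.
#' @param schedule a [phase_schedule()].
#' @param backend `"float"` or `"hw"`.
#' @param window_mode `"phase"`: average everything past the unstable time
#'   (70 samples at defaults); `"delta"`: average only the last `delta_t`
#'   ms of each phase.
#' @return the updated accumulators.
#' @export
accumulate_step <- function(acc, counter, x, V0a, V0, V1, s0, schedule,
                            backend = c("float", "hw"),
                            window_mode = c("phase", "delta")) {
  backend <- match.arg(backend)
  window_mode <- match.arg(window_mode)
  fl <- phase_flags(schedule, counter)
  t_phase <- if (fl$forward_enable) schedule$t_forward else schedule$t_target
  win <- if (window_mode == "phase") t_phase - schedule$delta_t
         else schedule$delta_t
  within <- if (fl$forward_enable) counter else counter - schedule$t_forward
  in_window <- if (window_mode == "phase") within > schedule$delta_t
               else within > t_phase - schedule$delta_t
  if (!in_window) return(acc)
  if (backend == "hw") {
    # the 1/window scaler sits on the dendritic/somatic potential paths;
    # presynaptic traces are accumulated raw
    sc <- function(v) fx_quantize(fx_const_mul(fx_quantize(1 / win), v))
    addV <- function(a, v) fx_quantize(a + sc(v))
    addS <- function(a, v) fx_quantize(a + v)
  } else {
    addV <- addS <- function(a, v) a + v
  }
  if (fl$forward_enable) {
    acc$n_f <- acc$n_f + 1L
    acc$V0a_f <- addV(acc$V0a_f, V0a)
    acc$V0_f <- addV(acc$V0_f, V0)
    acc$x_f <- addS(acc$x_f, x)
    acc$V1_f <- addV(acc$V1_f, V1)
    acc$s0_f <- addS(acc$s0_f, s0)
  } else {
    acc$n_t <- acc$n_t + 1L
    acc$V0a_t <- addV(acc$V0a_t, V0a)
    acc$V1_t <- addV(acc$V1_t, V1)
  }
  acc
}

# Phase statistics from the accumulators. Potentials become means (on the
# hardware backend the per-sample 1/window scaling already produced them);
# presynaptic traces stay window sums under the default presyn_stat = "sum"
# and are divided down under "mean".
finalize_accumulators <- function(acc, backend = "float",
                                  presyn_stat = "sum") {
  if (acc$n_f == 0L || acc$n_t == 0L) {
    stop("finalize_accumulators: both phases must have accumulated samples")
  }
  hw <- backend == "hw"
  vmean <- function(v, n) if (hw) v else v / n
  presyn <- function(v, n) {
    if (presyn_stat == "sum") v
    else if (hw) fx_quantize(fx_const_mul(fx_quantize(1 / n), v))
    else v / n
  }
  list(V0a_f = vmean(acc$V0a_f, acc$n_f), V0a_t = vmean(acc$V0a_t, acc$n_t),
       V0_f = vmean(acc$V0_f, acc$n_f),
       x_f = presyn(acc$x_f, acc$n_f),
       V1_f = vmean(acc$V1_f, acc$n_f), V1_t = vmean(acc$V1_t, acc$n_t),
       s0_f = presyn(acc$s0_f, acc$n_f))
}

#' Plateau potential of an apical mean
#'
#' The sigmoid (exact, or five-segment PWL on the hardware backend) of the
#' time-averaged apical dendritic potential of a phase.
#'
#' @param apical_mean numeric vector of windowed apical means.
#' @param backend `"float"` or `"hw"`.
#' @return plateau potentials in \[0, 1\].
#' @export
#' @examples
#' plateau_potential(0) # 0.5
plateau_potential <- function(apical_mean, backend = c("float", "hw")) {
  backend <- match.arg(backend)
  if (backend == "float") plogis(apical_mean)
  else pwl_eval(pwl_sigmoid5(), apical_mean, backend = "hw")
}

# sigma'(v) per backend: exact sigma(1-sigma), or the six-segment PWL.
sigmoid_deriv <- function(v, backend = "float") {
  if (backend == "float") plogis(v) * (1 - plogis(v))
  else pwl_eval(pwl_dsigmoid6(), v, backend = "hw")
}

#' Hidden-layer weight and bias update
#'
#' Per-neuron error `e_i = (alpha_t_i - alpha_f_i) * phi_max *
#' sigma'(V0bar_f_i)` from the two phases' plateau potentials; the update
#' is the rank-one outer product with the forward-phase mean input:
#' `W0 <- W0 + sign * eta0 * P0 * g_b/(g_l+g_b+g_a) * e %o% x_f`, and the
#' bias update is the same without the presynaptic factor.
#'
#' @param W0,b0 current weights (hidden x input) and biases.
#' @param acc finalized accumulators (a [new_accumulators()] object after a
#'   complete trial).
#' @param config a [learning_config()].
#' @param params a [network_params()].
#' @param backend `"float"` or `"hw"`.
#' @return list with updated `W0`, `b0`.
#' @export
hidden_update <- function(W0, b0, acc, config = learning_config(),
                          params = network_params(),
                          backend = c("float", "hw")) {
  backend <- match.arg(backend)
  m <- finalize_accumulators(acc, backend, config$presyn_stat)
  alpha_f <- plateau_potential(m$V0a_f, backend)
  alpha_t <- plateau_potential(m$V0a_t, backend)
  fac <- config$update_sign * params$eta0 * params$P0 *
    params$g_b / (params$g_l + params$g_b + params$g_a)
  if (backend == "hw") {
    e <- fx_quantize(shift_mul(abs(alpha_t - alpha_f),
                               sigmoid_deriv(m$V0_f, backend)) *
                       sign(alpha_t - alpha_f))
    e <- fx_quantize(fx_const_mul(params$phi_max, e))
    dW <- fx_quantize(outer(e, m$x_f,
                            function(ei, xj) sign(ei) * shift_mul(abs(ei), xj)))
    list(W0 = fx_quantize(W0 + fx_const_mul(fac, dW)),
         b0 = fx_quantize(b0 + fx_const_mul(fac, e)))
  } else {
    e <- (alpha_t - alpha_f) * params$phi_max *
      sigmoid_deriv(m$V0_f, backend)
    list(W0 = W0 + fac * (e %o% m$x_f), b0 = b0 + fac * e)
  }
}

#' Output-layer weight and bias update
#'
#' The per-output error is the difference of mean firing rates implied by
#' the phase-averaged somatic voltages, `phibar = phi_max *
#' sigma(V1bar)`, between target and forward phase:
#' `e_i = (phibar_t_i - phibar_f_i) * phi_max * sigma'(V1bar_f_i)`;
#' the update is `W1 <- W1 + sign * eta1 * P1 * g_d/(g_l+g_d) *
#' e %o% s0_f` and analogously for the bias.
#'
#' @inheritParams hidden_update
#' @param W1,b1 current weights (output x hidden) and biases.
#' @return list with updated `W1`, `b1`.
#' @export
output_update <- function(W1, b1, acc, config = learning_config(),
                          params = network_params(),
                          backend = c("float", "hw")) {
  backend <- match.arg(backend)
  m <- finalize_accumulators(acc, backend, config$presyn_stat)
  sig <- if (backend == "float") plogis else {
    function(v) pwl_eval(pwl_sigmoid5(), v, backend = "hw")
  }
  fac <- config$update_sign * params$eta1 * params$P1 *
    params$g_d / (params$g_l + params$g_d)
  if (backend == "hw") {
    phi_f <- fx_quantize(fx_const_mul(params$phi_max, sig(m$V1_f)))
    phi_t <- fx_quantize(fx_const_mul(params$phi_max, sig(m$V1_t)))
    e <- fx_quantize(shift_mul(abs(phi_t - phi_f),
                               sigmoid_deriv(m$V1_f, backend)) *
                       sign(phi_t - phi_f))
    e <- fx_quantize(fx_const_mul(params$phi_max, e))
    dW <- fx_quantize(outer(e, m$s0_f,
                            function(ei, sj) sign(ei) * shift_mul(abs(ei), sj)))
    list(W1 = fx_quantize(W1 + fx_const_mul(fac, dW)),
         b1 = fx_quantize(b1 + fx_const_mul(fac, e)))
  } else {
    phi_f <- params$phi_max * sig(m$V1_f)
    phi_t <- params$phi_max * sig(m$V1_t)
    e <- (phi_t - phi_f) * params$phi_max * sigmoid_deriv(m$V1_f, backend)
    list(W1 = W1 + fac * (e %o% m$s0_f), b1 = b1 + fac * e)
  }
}

#' Apply the end-of-trial plasticity step to a network
#'
#' Runs [hidden_update()] and [output_update()] once with the trial's
#' accumulators and returns the network with new `W0, b0, W1, b1`. The
#' feedback weights `Y` are left untouched, matching the fixed top-down
#' channel of the model.
#'
#' @param net an [build_network()] object.
#' @param acc accumulators of a completed trial.
#' @return the updated network.
#' @export
apply_trial_end <- function(net, acc) {
  h <- hidden_update(net$W0, net$b0, acc, net$config, net$params,
                     net$backend)
  o <- output_update(net$W1, net$b1, acc, net$config, net$params,
                     net$backend)
  net$W0 <- h$W0; net$b0 <- h$b0; net$W1 <- o$W1; net$b1 <- o$b1
  net
}
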