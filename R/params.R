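#' Network and neuron parameters
#'
#' Constructs the parameter set shared by all neurons and by the learning
#' rule. The defaults are the standard operating point of the model: a 1 ms
#' integration step, a 200 Hz maximum firing rate, double-exponential
#' synaptic kernels with 10/3 ms time constants, and conductance-based
#' nudging with symmetric reversal values of +/-12.
#'
#' @param dt integration step (ms).
#' @param phi_max maximum firing rate (spikes/ms); 0.2 corresponds to 200 Hz.
#' @param tau_l,tau_s long and short time constants of the synaptic kernel (ms).
#' @param E_E,E_I excitatory and inhibitory nudging reversal values.
#' @param g_d conductance from the basal dendrite to the soma (output layer).
#' @param g_a,g_b conductances from apical/basal dendrites to the soma
#'   (hidden layer). `g_a = 0` by default: the apical compartment then
#'   influences learning only, not the somatic voltage.
#' @param g_l leak conductance.
#' @param V_res resting potential.
#' @param C_m membrane capacitance.
#' @param delta_t unstable time (ms): the initial part of each phase
#'   excluded from all phase averages while voltages settle.
#' @param eta0,eta1 learning rates of the hidden and output layer.
#' @param P0,P1 scaling factors of the hidden and output layer updates.
#' @param t_forward,t_target durations of the forward and target phase (ms).
#'
#' @return An object of class `network_params`.
#' @export
#' @examples
#' p <- network_params()
#' p$phi_max * 1000 # maximum rate in Hz
network_params <- function(dt = 1, phi_max = 0.2, tau_l = 10, tau_s = 3,
                           E_E = 12, E_I = -12, g_d = 0.6, g_a = 0,
                           g_b = 0.6, g_l = 0.1, V_res = 0, C_m = 1,
                           delta_t = 30, eta0 = 0.01, eta1 = 0.01,
                           P0 = 20 / phi_max, P1 = 20 / phi_max^2,
                           t_forward = 100, t_target = 100) {
  p <- list(dt = dt, phi_max = phi_max, tau_l = tau_l, tau_s = tau_s,
            E_E = E_E, E_I = E_I, g_d = g_d, g_a = g_a, g_b = g_b,
            g_l = g_l, V_res = V_res, C_m = C_m, delta_t = delta_t,
            eta0 = eta0, eta1 = eta1, P0 = P0, P1 = P1,
            t_forward = t_forward, t_target = t_target)
  validate_network_params(p)
  class(p) <- "network_params"
  p
}

validate_network_params <- function(p) {
  stopifnot(p$tau_l > p$tau_s, p$tau_s > 0, p$C_m > 0, p$dt > 0,
            p$phi_max > 0, p$delta_t >= 0,
            p$t_forward > p$delta_t, p$t_target > p$delta_t)
  for (g in c("g_d", "g_a", "g_b", "g_l")) {
    if (p[[g]] < 0) stop("conductance ", g, " must be >= 0")
  }
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("MLIF network parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Learning-rule configuration
#'
#' Options of the two-phase plateau-potential rule that are not plain
#' physical parameters.
#'
#' @param update_sign sign convention of the weight update. The update term
#'   is `update_sign * eta * P * factor * error (x) presynaptic-mean` added
#'   to the weights. With `+1` (the default) the forward-phase output
#'   statistics move toward the nudged target-phase statistics, i.e. the
#'   rule descends the output error. `-1` applies the opposite convention,
#'   which drives the forward output away from the target and does not
#'   learn; the option exists so both conventions can be exercised and
#'   compared (see the vignette for the fixed-point analysis behind the
#'   default).
#' @param presyn_stat how the presynaptic phase statistics (the filtered
#'   input trace and the filtered hidden activity) enter the weight
#'   updates: `"sum"` (default) accumulates them over the averaging window
#'   as the digital circuit does — the 1/window scaler sits only on the
#'   dendritic-potential paths — while `"mean"` divides them by the window
#'   length like every other phase statistic. The choice rescales the
#'   weight updates (not the bias updates) by the window length; see the
#'   vignette.
#' @param plateau_window_mode `"phase"` (default): every phase average uses
#'   all samples of the phase past the unstable time (70 samples at the
#'   default 100 ms phase and 30 ms unstable time), matching the digital
#'   accumulate-and-scale-by-1/70 implementation. `"delta"`: averages use
#'   only the last `delta_t` ms of each phase.
#'
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(update_sign = 1,
                            presyn_stat = c("sum", "mean"),
                            plateau_window_mode = c("phase", "delta")) {
  stopifnot(update_sign %in% c(-1, 1))
  presyn_stat <- match.arg(presyn_stat)
  plateau_window_mode <- match.arg(plateau_window_mode)
  structure(list(update_sign = update_sign, presyn_stat = presyn_stat,
                 plateau_window_mode = plateau_window_mode),
            class = "learning_config")
}
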