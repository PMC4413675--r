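#' Silicon-neuron parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdEx) point
#' neuron emulated by the silicon soma.  All membrane-related quantities are
#' expressed in dimensionless normalized units (resting level 0, spike peak
#' 1); time constants are in seconds.  The hardware exposes its knobs as
#' subthreshold bias currents, not SI values, so the defaults here are free
#' choices that respect the orderings the circuit imposes
#' (`rest_level < exp_threshold < peak_level`).
#'
#' The chip can latch one of two leak time constants and one of two
#' refractory settings per neuron, for at most four neuron types; a full
#' device configuration therefore holds up to four `neuron_params` sets
#' (see [chip_config()]).
#'
#' @param tau_mem Membrane leak time constant (s).  The membrane capacitance
#'   is normalized so that `C = tau_mem * leak_conductance`.
#' @param t_ref Absolute refractory period (s); the membrane is clamped at
#'   `reset_level` for this long after each spike.
#' @param leak_conductance Leak conductance (1/s, dimensionless units).
#' @param rest_level Resting potential (fixed point with zero input).
#' @param exp_slope Sharpness `Delta_T` of the exponential spike-initiation
#'   term.  `0` selects the hard-threshold (leaky integrate-and-fire) limit,
#'   in which a spike is emitted as soon as the membrane reaches
#'   `exp_threshold`.
#' @param exp_threshold Soft threshold `V_T` where the sodium positive
#'   feedback ignites.
#' @param peak_level Spike detection level `V_peak`.
#' @param reset_level Post-spike reset potential (tunable on the hardware;
#'   raising it at fixed input increases the firing rate).
#' @param ahp_b After-hyperpolarization (adaptation) increment added to the
#'   adaptation current at each spike; `0` disables spike-frequency
#'   adaptation.
#' @param ahp_tau Decay time constant of the adaptation current (s).
#' @param nmda_gate_threshold Membrane level above which the NMDA voltage
#'   gate opens.
#' @param nmda_gate_enabled Logical; when `TRUE` the NMDA-type row current
#'   only reaches the soma while the membrane exceeds
#'   `nmda_gate_threshold`.
#'
#' @return An object of class `neuron_params` (a validated list).
#' @seealso [step_neuron()], [fi_curve()], [chip_config()]
#' @export
#' @examples
#' p <- neuron_params()
#' p$tau_mem
neuron_params <- function(tau_mem = 0.020,
                          t_ref = 0.002,
                          leak_conductance = 0.05,
                          rest_level = 0,
                          exp_slope = 0.02,
                          exp_threshold = 0.8,
                          peak_level = 1,
                          reset_level = 0,
                          ahp_b = 0,
                          ahp_tau = 0.1,
                          nmda_gate_threshold = 0.2,
                          nmda_gate_enabled = FALSE) {
  p <- list(tau_mem = tau_mem, t_ref = t_ref,
            leak_conductance = leak_conductance,
            rest_level = rest_level, exp_slope = exp_slope,
            exp_threshold = exp_threshold, peak_level = peak_level,
            reset_level = reset_level, ahp_b = ahp_b, ahp_tau = ahp_tau,
            nmda_gate_threshold = nmda_gate_threshold,
            nmda_gate_enabled = isTRUE(nmda_gate_enabled))
  validate_neuron_params(p)
  class(p) <- "neuron_params"
  p
}

validate_neuron_params <- function(p) {
  num <- c("tau_mem", "t_ref", "leak_conductance", "rest_level", "exp_slope",
           "exp_threshold", "peak_level", "reset_level", "ahp_b", "ahp_tau",
           "nmda_gate_threshold")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("neuron_params: field '", f, "' must be a finite number",
           call. = FALSE)
  }
  if (p$tau_mem <= 0 || p$ahp_tau <= 0)
    stop("neuron_params: time constants must be > 0", call. = FALSE)
  if (p$t_ref < 0)
    stop("neuron_params: t_ref must be >= 0", call. = FALSE)
  if (p$leak_conductance <= 0)
    stop("neuron_params: leak_conductance must be > 0", call. = FALSE)
  if (!(p$rest_level < p$exp_threshold && p$exp_threshold < p$peak_level))
    stop("neuron_params: need rest_level < exp_threshold < peak_level",
         call. = FALSE)
  if (p$reset_level >= p$peak_level)
    stop("neuron_params: reset_level must be < peak_level", call. = FALSE)
  if (p$exp_slope < 0)
    stop("neuron_params: exp_slope must be >= 0 (0 = hard threshold)",
         call. = FALSE)
  if (p$ahp_b < 0)
    stop("neuron_params: ahp_b must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  tau_mem = %g s, t_ref = %g s, g_leak = %g\n",
              x$tau_mem, x$t_ref, x$leak_conductance))
  cat(sprintf("  rest = %g, Delta_T = %g, V_T = %g, V_peak = %g, V_reset = %g\n",
              x$rest_level, x$exp_slope, x$exp_threshold, x$peak_level,
              x$reset_level))
  cat(sprintf("  adaptation: b = %g, tau_ahp = %g s; NMDA gate: %s (thr %g)\n",
              x$ahp_b, x$ahp_tau,
              if (x$nmda_gate_enabled) "on" else "off",
              x$nmda_gate_threshold))
  invisible(x)
}

#' Neuron state
#'
#' Dynamic state of one silicon neuron: the membrane variable (the
#' hardware's membrane current, equivalent to the membrane potential of the
#' point-neuron model), the adaptation current, the calcium trace integrated
#' by the post-synaptic learning block, and refractory book-keeping.
#'
#' @param v Membrane variable.
#' @param i_ahp Adaptation (after-hyperpolarization) current.
#' @param ca Calcium trace (running average of the neuron's own spiking);
#'   must be non-negative.
#' @param ref_until Absolute time (s) at which the refractory period ends.
#' @param last_spike Time of the most recent spike, or `NA` if none.
#'
#' @return An object of class `neuron_state`.
#' @export
#' @examples
#' s <- neuron_state()
#' s$ca
neuron_state <- function(v = 0, i_ahp = 0, ca = 0, ref_until = -Inf,
                         last_spike = NA_real_) {
  if (!is.finite(v) || !is.finite(i_ahp) || !is.finite(ca))
    stop("neuron_state: v, i_ahp and ca must be finite", call. = FALSE)
  if (ca < 0) stop("neuron_state: ca must be >= 0", call. = FALSE)
  s <- list(v = v, i_ahp = i_ahp, ca = ca, ref_until = ref_until,
            last_spike = last_spike)
  class(s) <- "neuron_state"
  s
}

#' Spike-driven plasticity parameters
#'
#' Parameters of the bistable spike-driven learning rule realized by the
#' long-term-plasticity synapse array together with the neuron's
#' post-synaptic comparator block.  On each pre-synaptic spike the internal
#' weight `w` jumps up by `dw_plus` if the post-synaptic membrane is above
#' `theta_mem` and the calcium trace lies in `(theta1, theta3)`, and jumps
#' down by `dw_minus` if the membrane is below `theta_mem` and calcium lies
#' in `(theta1, theta2)`; otherwise learning is stopped and `w` is left
#' unchanged.  Between spikes `w` drifts toward `w_max` or `w_min` depending
#' on its position relative to `theta_w` (bistability), and the synaptic
#' efficacy delivered on a pre-spike is a thresholded function of `w`.
#'
#' Default values are normalized free choices that satisfy the required
#' orderings `theta1 < theta2 < theta3` and `w_min < theta_w < w_max`.
#'
#' @param dw_plus,dw_minus Up/down jump amplitudes of the internal weight.
#' @param theta_mem Membrane comparator threshold.
#' @param theta1,theta2,theta3 Calcium thresholds delimiting the
#'   potentiation window `(theta1, theta3)` and depression window
#'   `(theta1, theta2)`.
#' @param theta_w Bistability threshold separating the basins of the two
#'   stable states.
#' @param c_drift_up,c_drift_dn Drift rates (per second) toward `w_max` and
#'   `w_min`.
#' @param w_min,w_max Bounds of the internal weight.
#' @param j_max Maximum synaptic efficacy delivered to the row integrator.
#' @param theta_j Efficacy threshold on `w` (inclusive: `w >= theta_j`
#'   delivers `j_max` in the hard form).
#' @param efficacy_form `"hard"` (default) or `"sigmoid"`.
#' @param sigmoid_slope Slope scale of the sigmoid efficacy form.
#' @param ca_jump Calcium increment per post-synaptic spike.
#' @param ca_tau Calcium trace decay time constant (s).
#' @param learning_enabled Logical; `FALSE` freezes all jump updates (the
#'   drift still acts, so programmed bistable states are retained).
#'
#' @return An object of class `plasticity_params`.
#' @seealso [pre_spike_update()], [drift_weight()], [efficacy()],
#'   [stop_learning_flags()]
#' @export
plasticity_params <- function(dw_plus = 0.1,
                              dw_minus = 0.1,
                              theta_mem = 0.5,
                              theta1 = 0.1,
                              theta2 = 0.35,
                              theta3 = 0.9,
                              theta_w = 0.5,
                              c_drift_up = 0.5,
                              c_drift_dn = 0.5,
                              w_min = 0,
                              w_max = 1,
                              j_max = 1,
                              theta_j = 0.5,
                              efficacy_form = c("hard", "sigmoid"),
                              sigmoid_slope = 0.05,
                              ca_jump = 0.1,
                              ca_tau = 0.2,
                              learning_enabled = TRUE) {
  efficacy_form <- match.arg(efficacy_form)
  p <- list(dw_plus = dw_plus, dw_minus = dw_minus, theta_mem = theta_mem,
            theta1 = theta1, theta2 = theta2, theta3 = theta3,
            theta_w = theta_w, c_drift_up = c_drift_up,
            c_drift_dn = c_drift_dn, w_min = w_min, w_max = w_max,
            j_max = j_max, theta_j = theta_j, efficacy_form = efficacy_form,
            sigmoid_slope = sigmoid_slope, ca_jump = ca_jump,
            ca_tau = ca_tau, learning_enabled = isTRUE(learning_enabled))
  validate_plasticity_params(p)
  class(p) <- "plasticity_params"
  p
}

validate_plasticity_params <- function(p) {
  if (!(p$theta1 < p$theta2 && p$theta2 < p$theta3))
    stop("plasticity_params: need theta1 < theta2 < theta3", call. = FALSE)
  if (!(p$w_min < p$theta_w && p$theta_w < p$w_max))
    stop("plasticity_params: need w_min < theta_w < w_max", call. = FALSE)
  if (p$dw_plus < 0 || p$dw_minus < 0)
    stop("plasticity_params: jump amplitudes must be >= 0", call. = FALSE)
  if (p$c_drift_up < 0 || p$c_drift_dn < 0)
    stop("plasticity_params: drift rates must be >= 0", call. = FALSE)
  if (p$theta_j <= p$w_min || p$theta_j >= p$w_max)
    stop("plasticity_params: theta_j must lie inside (w_min, w_max)",
         call. = FALSE)
  if (p$ca_tau <= 0)
    stop("plasticity_params: ca_tau must be > 0", call. = FALSE)
  if (p$ca_jump < 0)
    stop("plasticity_params: ca_jump must be >= 0", call. = FALSE)
  if (p$sigmoid_slope <= 0)
    stop("plasticity_params: sigmoid_slope must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params>\n")
  cat(sprintf("  jumps: +%g / -%g; theta_mem = %g\n",
              x$dw_plus, x$dw_minus, x$theta_mem))
  cat(sprintf("  calcium thresholds: (%g, %g, %g); ca_jump = %g, ca_tau = %g s\n",
              x$theta1, x$theta2, x$theta3, x$ca_jump, x$ca_tau))
  cat(sprintf("  bistability: theta_w = %g, drift (+%g, -%g)/s, w in [%g, %g]\n",
              x$theta_w, x$c_drift_up, x$c_drift_dn, x$w_min, x$w_max))
  cat(sprintf("  efficacy: %s, J_max = %g, theta_J = %g; learning %s\n",
              x$efficacy_form, x$j_max, x$theta_j,
              if (x$learning_enabled) "enabled" else "frozen"))
  invisible(x)
}

#' Short-term depression parameters
#'
#' The excitatory branch of a programmable (short-term-plasticity array)
#' synapse removes a fixed amount of charge from its depression capacitor at
#' each pre-synaptic pulse, transiently reducing the delivered EPSC, and
#' recovers toward full efficacy during silence.  The recovery is modeled as
#' first order with time constant `recovery_tau`; the depression is
#' subtractive with step `depress_amount`.
#'
#' @param depress_amount Efficacy subtracted per pre-synaptic spike
#'   (in `[0, 1]`).
#' @param recovery_tau Recovery time constant (s).
#' @param std_enabled Logical; `FALSE` makes programmable synapses
#'   time-invariant (no depression).
#'
#' @return An object of class `std_params`.
#' @seealso [std_on_pre()], [std_recover()]
#' @export
std_params <- function(depress_amount = 0.2, recovery_tau = 0.05,
                       std_enabled = FALSE) {
  if (depress_amount < 0 || depress_amount > 1)
    stop("std_params: depress_amount must be in [0, 1]", call. = FALSE)
  if (recovery_tau <= 0)
    stop("std_params: recovery_tau must be > 0", call. = FALSE)
  p <- list(depress_amount = depress_amount, recovery_tau = recovery_tau,
            std_enabled = isTRUE(std_enabled))
  class(p) <- "std_params"
  p
}
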