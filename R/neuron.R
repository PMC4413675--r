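## AdEx soma dynamics + post-synaptic learning comparators.
##
## The membrane obeys (normalized units, C = tau_mem * g_L):
##   C dv/dt = -g_L (v - rest) + g_L * Delta_T * exp((v - V_T)/Delta_T)
##             - i_ahp + i_syn
## with forward-Euler integration.  The exponential argument is clamped
## (EXP_ARG_MAX) so a step cannot overflow; the spike is detected at
## v >= V_peak and the overshoot is discarded by the reset.  In the
## hard-threshold limit Delta_T = 0 the exponential term vanishes and the
## ignition is instantaneous, so the spike is detected at v >= V_T.

EXP_ARG_MAX <- 16

## Exponential spike-initiation drive, clamped.  Vectorized over v.
adex_exp_drive <- function(v, p) {
  if (p$exp_slope <= 0) return(0 * v)
  p$leak_conductance * p$exp_slope *
    exp(pmin((v - p$exp_threshold) / p$exp_slope, EXP_ARG_MAX))
}

spike_threshold <- function(p) {
  if (p$exp_slope <= 0) p$exp_threshold else p$peak_level
}

#' Advance one neuron by one time step
#'
#' Forward-Euler update of the adaptive exponential integrate-and-fire
#' membrane, with subtractive spike-frequency adaptation, refractory clamp
#' at the reset level, and the calcium increment applied at spike time.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @param i_syn Net synaptic input current (dimensionless, finite).
#' @param t Current time (s).
#' @param dt Time step (s), `> 0`.
#' @param ca_jump Calcium increment added at each spike (default matches
#'   the [plasticity_params()] default).
#'
#' @return A list with elements `state` (the updated [neuron_state()]) and
#'   `spiked` (logical).
#' @export
#' @examples
#' s <- neuron_state()
#' p <- neuron_params()
#' step_neuron(s, p, i_syn = 0, t = 0, dt = 1e-4)$spiked
step_neuron <- function(state, params, i_syn, t, dt, ca_jump = 0.1) {
  if (!is.numeric(dt) || dt <= 0) stop("step_neuron: dt must be > 0")
  if (!is.finite(i_syn)) stop("step_neuron: non-finite i_syn")
  if (!is.finite(state$v) || !is.finite(state$i_ahp))
    stop("step_neuron: non-finite neuron state (numerical blow-up?)")
  p <- params
  v <- state$v
  i_ahp <- state$i_ahp * exp(-dt / p$ahp_tau)
  in_ref <- t < state$ref_until
  if (in_ref) {
    v <- p$reset_level
  } else {
    cm <- p$tau_mem * p$leak_conductance
    dv <- (-p$leak_conductance * (v - p$rest_level) +
             adex_exp_drive(v, p) - i_ahp + i_syn) / cm
    v <- v + dv * dt
  }
  spiked <- !in_ref && v >= spike_threshold(p)
  ca <- state$ca
  ref_until <- state$ref_until
  last_spike <- state$last_spike
  if (spiked) {
    v <- p$reset_level
    i_ahp <- i_ahp + p$ahp_b
    ca <- ca + ca_jump
    ref_until <- t + p$t_ref
    last_spike <- t
  }
  list(state = neuron_state(v = v, i_ahp = i_ahp, ca = ca,
                            ref_until = ref_until,
                            last_spike = last_spike),
       spiked = spiked)
}

#' Firing rate versus injected current
#'
#' Simulates one neuron per current value under constant injection and
#' returns the mean firing rate.  Rates are measured from the mean
#' inter-spike interval (time between first and last spike), which for
#' deterministic constant-input firing removes the edge bias of a simple
#' count; currents that elicit fewer than two spikes report the count-based
#' rate (0 Hz for subthreshold currents).
#'
#' @param params A [neuron_params()].
#' @param currents Numeric vector of injection currents.
#' @param duration Simulated time per current (s).
#' @param dt Integration step (s).
#'
#' @return Numeric vector of rates (Hz), one per current, non-decreasing in
#'   the current.
#' @export
#' @examples
#' fi_curve(neuron_params(), c(0, 0.05, 0.08), duration = 1)
fi_curve <- function(params, currents, duration = 2, dt = 1e-4) {
  if (any(!is.finite(currents))) stop("fi_curve: non-finite current")
  p <- params
  n <- length(currents)
  v <- rep(p$rest_level, n)
  i_ahp <- numeric(n)
  ref_until <- rep(-Inf, n)
  n_spk <- integer(n)
  t_first <- rep(NA_real_, n)
  t_last <- rep(NA_real_, n)
  cm <- p$tau_mem * p$leak_conductance
  thr <- spike_threshold(p)
  dec_ahp <- exp(-dt / p$ahp_tau)
  n_steps <- ceiling(duration / dt)
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    i_ahp <- i_ahp * dec_ahp
    in_ref <- t < ref_until
    dv <- (-p$leak_conductance * (v - p$rest_level) +
             adex_exp_drive(v, p) - i_ahp + currents) / cm
    v <- ifelse(in_ref, p$reset_level, v + dv * dt)
    spiked <- !in_ref & v >= thr
    if (any(spiked)) {
      v[spiked] <- p$reset_level
      i_ahp[spiked] <- i_ahp[spiked] + p$ahp_b
      ref_until[spiked] <- t + p$t_ref
      t_first[spiked & is.na(t_first)] <- t
      t_last[spiked] <- t
      n_spk[spiked] <- n_spk[spiked] + 1L
    }
  }
  rate <- ifelse(n_spk >= 2L, (n_spk - 1L) / (t_last - t_first),
                 n_spk / duration)
  rate[n_spk == 0L] <- 0
  rate
}

#' Decay the calcium trace
#'
#' Exact exponential decay of the post-synaptic calcium concentration over
#' `dt`; the per-spike increments are applied inside [step_neuron()].
#'
#' @param state A [neuron_state()].
#' @param dt Elapsed time (s), `>= 0`.
#' @param ca_tau Calcium decay time constant (s), `> 0`.
#'
#' @return The updated [neuron_state()].
#' @export
#' @examples
#' s <- neuron_state(ca = 1)
#' update_calcium(s, dt = 0.2, ca_tau = 0.2)$ca  # exp(-1)
update_calcium <- function(state, dt, ca_tau) {
  if (ca_tau <= 0) stop("update_calcium: ca_tau must be > 0")
  if (dt < 0) stop("update_calcium: dt must be >= 0")
  state$ca <- state$ca * exp(-dt / ca_tau)
  state
}

#' Stop-learning comparator flags
#'
#' Evaluates the post-synaptic side of the spike-driven learning rule: the
#' up-jump is enabled when the membrane is above the comparator threshold
#' and the calcium trace lies strictly inside the potentiation window
#' `(theta1, theta3)`; the down-jump is enabled when the membrane is below
#' threshold and calcium lies inside `(theta1, theta2)`.  Outside these
#' windows learning is stopped.  These are the signals broadcast in
#' parallel to all plastic synapses afferent to the neuron.
#'
#' @param state A [neuron_state()] (fields `v` and `ca` are read).
#' @param p A [plasticity_params()].
#'
#' @return A list with logical elements `up_enabled` and `dn_enabled`
#'   (never both `TRUE`).
#' @export
#' @examples
#' stop_learning_flags(neuron_state(v = 0.7, ca = 0.5), plasticity_params())
stop_learning_flags <- function(state, p) {
  if (!(p$theta1 < p$theta2 && p$theta2 < p$theta3))
    stop("stop_learning_flags: misordered calcium thresholds")
  list(
    up_enabled = state$v > p$theta_mem && state$ca > p$theta1 &&
      state$ca < p$theta3,
    dn_enabled = state$v < p$theta_mem && state$ca > p$theta1 &&
      state$ca < p$theta2
  )
}

#' Closed-form leaky integrate-and-fire rate
#'
#' Reference firing rate of a hard-threshold leaky integrate-and-fire
#' neuron under constant current `i`:
#' `f = 1 / (t_ref + tau_mem * log(i / (i - g_L * V_T)))` for
#' suprathreshold currents, `0` otherwise (threshold measured from the
#' resting level, reset at rest).  Used as the independent oracle for the
#' simulated f-I curve in the `exp_slope = 0`, no-adaptation limit.
#'
#' @param params A [neuron_params()] (uses `t_ref`, `tau_mem`,
#'   `leak_conductance`, `exp_threshold`, `rest_level`).
#' @param currents Numeric vector of injection currents.
#' @return Numeric vector of rates (Hz).
#' @export
lif_rate <- function(params, currents) {
  p <- params
  gl <- p$leak_conductance
  vth <- p$exp_threshold - p$rest_level
  vapply(currents, function(i) {
    if (i <= gl * vth) return(0)
    1 / (p$t_ref + p$tau_mem * log(i / (i - gl * vth)))
  }, numeric(1))
}
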