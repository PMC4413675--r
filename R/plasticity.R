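## Bistable spike-driven learning rule of the long-term plasticity array.
## Jump updates are evaluated at pre-synaptic spike arrival against the
## post-synaptic membrane and calcium (stop-learning gating); between
## events the internal variable drifts toward one of the two stable
## states.  All functions are vectorized over w (and, where meaningful,
## over v_mem/ca), since the simulator updates whole array columns at
## once.

#' Pre-synaptic spike weight update
#'
#' On arrival of a pre-synaptic spike the internal weight jumps up by
#' `dw_plus` when the post-synaptic membrane exceeds `theta_mem` and the
#' calcium trace lies strictly in `(theta1, theta3)`; it jumps down by
#' `dw_minus` when the membrane is below `theta_mem` and calcium lies in
#' `(theta1, theta2)`; otherwise (stop-learning) it is unchanged.  The
#' result is clipped to `[w_min, w_max]`.  The post-synaptic state is read
#' at spike arrival, before the EPSC of the same spike is applied.
#'
#' @param w Internal weight(s) in `[w_min, w_max]`.
#' @param v_mem Post-synaptic membrane value(s) at pre-spike arrival.
#' @param ca Post-synaptic calcium trace(s) at pre-spike arrival.
#' @param p A [plasticity_params()].
#'
#' @return Updated weight(s).  When `p$learning_enabled` is `FALSE`, `w`
#'   is returned unchanged.
#' @export
#' @examples
#' p <- plasticity_params()
#' pre_spike_update(0.4, v_mem = 0.7, ca = 0.5, p)  # up jump -> 0.5
pre_spike_update <- function(w, v_mem, ca, p) {
  if (!p$learning_enabled) return(w)
  up <- v_mem > p$theta_mem & ca > p$theta1 & ca < p$theta3
  dn <- v_mem < p$theta_mem & ca > p$theta1 & ca < p$theta2
  w2 <- w + ifelse(up, p$dw_plus, 0) - ifelse(dn, p$dw_minus, 0)
  pmin(pmax(w2, p$w_min), p$w_max)
}

#' Bistability drift
#'
#' Between events the internal weight is driven at constant rate toward
#' `w_max` if it is above the bistability threshold `theta_w`, and toward
#' `w_min` if below; a weight exactly at `theta_w` stays put.  The update
#' is the closed form of the piecewise-linear flow, so applying it lazily
#' over a long interval equals repeated small steps exactly (the flow
#' cannot cross `theta_w`).
#'
#' @param w Internal weight(s).
#' @param dt Elapsed time (s), `>= 0`.
#' @param p A [plasticity_params()].
#' @return Drifted weight(s), saturating at the bounds.
#' @export
#' @examples
#' drift_weight(0.6, dt = 0.2, plasticity_params())  # 0.7
drift_weight <- function(w, dt, p) {
  if (dt < 0) stop("drift_weight: dt must be >= 0")
  up <- w > p$theta_w
  dn <- w < p$theta_w
  w[up] <- pmin(w[up] + p$c_drift_up * dt, p$w_max)
  w[dn] <- pmax(w[dn] - p$c_drift_dn * dt, p$w_min)
  w
}

#' Synaptic efficacy from the internal weight
#'
#' The efficacy actually delivered to the row integrator on a pre-spike is
#' a thresholded read-out of the internal variable: in the hard form
#' (default) `J = J_max` when `w >= theta_j` (boundary inclusive) and `0`
#' otherwise; the sigmoid form uses a logistic of slope `sigmoid_slope`.
#'
#' @param w Internal weight(s).
#' @param p A [plasticity_params()].
#' @return Efficacy value(s) in `[0, J_max]`.
#' @export
#' @examples
#' efficacy(c(0.3, 0.5, 0.7), plasticity_params())
efficacy <- function(w, p) {
  switch(p$efficacy_form,
         hard = ifelse(w >= p$theta_j, p$j_max, 0),
         sigmoid = p$j_max * stats::plogis((w - p$theta_j) / p$sigmoid_slope))
}

#' Bistable plastic synapse element
#'
#' One element of the long-term plasticity array: the analog internal
#' weight plus the three configuration latches (weight monitor, broadcast
#' activation, recurrent activation).
#'
#' @param w Internal weight.
#' @param mon_en,bc_en,rec_en Configuration latches.
#' @return An object of class `ltp_synapse`.
#' @export
ltp_synapse <- function(w = 0, mon_en = FALSE, bc_en = FALSE,
                        rec_en = FALSE) {
  s <- list(w = w, mon_en = isTRUE(mon_en), bc_en = isTRUE(bc_en),
            rec_en = isTRUE(rec_en))
  class(s) <- "ltp_synapse"
  s
}

#' Program a bistable synapse to one of its stable states
#'
#' The SET block forces the internal variable directly to the high or low
#' bound, which the drift then holds indefinitely.  This is how networks
#' are programmed without learning (e.g. attractor connectivity).
#'
#' @param syn An [ltp_synapse()].
#' @param high Logical: `TRUE` sets `w_max`, `FALSE` sets `w_min`.
#' @param p A [plasticity_params()] supplying the bounds.
#' @return The updated [ltp_synapse()].
#' @export
set_weight <- function(syn, high, p = plasticity_params()) {
  syn$w <- if (isTRUE(high)) p$w_max else p$w_min
  syn
}
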