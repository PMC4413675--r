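## Linear DPI row integrators and the programmable (short-term plasticity)
## synapse element.  The differential-pair integrator is modeled in its
## linear operating range: a first-order low-pass filter whose output
## current decays exponentially and receives an instantaneous
## charge-proportional jump per input spike (the hardware pulse extender is
## folded into the jump scale).  Because all synapses of a row share one
## integrator, simultaneous spikes superpose linearly and the mean
## steady-state current depends only on the product (rate x weight) -- the
## property that lets a single time-multiplexed "virtual synapse" stand in
## for many independent inputs.

#' Differential-pair-integrator state
#'
#' @param tau Integrator time constant (s), `> 0`.
#' @param jump_scale Charge delivered per unit effective weight per spike.
#' @param i_out Current output (non-negative).
#'
#' @return An object of class `dpi_state`.
#' @seealso [dpi_decay()], [dpi_on_spike()]
#' @export
dpi_state <- function(tau = 0.02, jump_scale = 1, i_out = 0) {
  if (tau <= 0) stop("dpi_state: tau must be > 0", call. = FALSE)
  if (i_out < 0) stop("dpi_state: i_out must be >= 0", call. = FALSE)
  s <- list(i_out = i_out, tau = tau, jump_scale = jump_scale)
  class(s) <- "dpi_state"
  s
}

#' Decay a DPI integrator
#'
#' Exact exponential decay over `dt` (unconditionally stable; two decays of
#' `dt/2` compose to one of `dt`).
#'
#' @param s A [dpi_state()].
#' @param dt Elapsed time (s), `>= 0`.
#' @return The updated [dpi_state()].
#' @export
#' @examples
#' dpi_decay(dpi_state(tau = 0.02, i_out = 1), dt = 0.02)$i_out  # exp(-1)
dpi_decay <- function(s, dt) {
  if (dt < 0) stop("dpi_decay: dt must be >= 0")
  s$i_out <- s$i_out * exp(-dt / s$tau)
  s
}

#' Deliver one spike to a DPI integrator
#'
#' Adds `jump_scale * effective_weight` to the output current.  Under
#' Poisson input at rate `nu` and weight `w` the steady-state mean current
#' is `jump_scale * w * nu * tau`.
#'
#' @param s A [dpi_state()].
#' @param effective_weight Non-negative weight of the arriving spike.
#' @return The updated [dpi_state()].
#' @export
dpi_on_spike <- function(s, effective_weight) {
  if (effective_weight < 0)
    stop("dpi_on_spike: effective_weight must be >= 0")
  s$i_out <- s$i_out + s$jump_scale * effective_weight
  s
}

#' Programmable (short-term plasticity array) synapse element
#'
#' One element of the 256x256 programmable array: a two-bit weight latch,
#' an excitatory/inhibitory latch, broadcast/recurrent activation latches,
#' and the short-term depression efficacy variable `std_x` (fraction of the
#' programmed weight currently available, baseline 1).
#'
#' @param weight_level Integer weight level in `{0, 1, 2, 3}`.
#' @param is_excitatory Logical latch selecting the excitatory (with STD)
#'   or inhibitory branch.
#' @param bc_en,rec_en Broadcast / recurrent activation latches.
#' @param std_x Available efficacy in `[0, 1]`.
#'
#' @return An object of class `stp_synapse`.
#' @export
stp_synapse <- function(weight_level = 0L, is_excitatory = TRUE,
                        bc_en = FALSE, rec_en = FALSE, std_x = 1) {
  if (!weight_level %in% 0:3)
    stop("stp_synapse: weight_level must be in {0,1,2,3}", call. = FALSE)
  if (std_x < 0 || std_x > 1)
    stop("stp_synapse: std_x must be in [0, 1]", call. = FALSE)
  s <- list(weight_level = as.integer(weight_level),
            is_excitatory = isTRUE(is_excitatory),
            bc_en = isTRUE(bc_en), rec_en = isTRUE(rec_en),
            std_x = std_x, std_baseline = 1)
  class(s) <- "stp_synapse"
  s
}

#' Two-bit weight DAC levels
#'
#' Maps weight levels `{0,1,2,3}` to four equidistant weights
#' `{0, 1/3, 2/3, 1} * w_unit`.
#'
#' @param level Integer vector of levels in `{0,1,2,3}`.
#' @param w_unit Full-scale weight.
#' @return Numeric weights.
#' @export
base_weight <- function(level, w_unit = 1) {
  if (any(!level %in% 0:3))
    stop("base_weight: level must be in {0,1,2,3}")
  (level / 3) * w_unit
}

#' Short-term depression: pre-synaptic spike
#'
#' Returns the EPSC weight generated by a pre-synaptic spike at an
#' excitatory programmable synapse and applies the subtractive depression.
#' The EPSC is sampled *before* the depression step, so the first spike of
#' a rested burst is full-size; `std_x` is then reduced by
#' `depress_amount` (floored at 0).
#'
#' @param syn An excitatory [stp_synapse()].
#' @param p An [std_params()] with `std_enabled = TRUE`.
#' @param w_unit Full-scale weight of the two-bit DAC.
#' @return A list with `syn` (updated synapse) and `epsc_weight`.
#' @export
std_on_pre <- function(syn, p, w_unit = 1) {
  if (!syn$is_excitatory)
    stop("std_on_pre: inhibitory synapses have no depression branch")
  if (!p$std_enabled)
    stop("std_on_pre: short-term depression is not enabled")
  epsc <- base_weight(syn$weight_level, w_unit) * syn$std_x
  syn$std_x <- max(syn$std_x - p$depress_amount, 0)
  list(syn = syn, epsc_weight = epsc)
}

#' Short-term depression: recovery during silence
#'
#' First-order recovery of the available efficacy toward baseline:
#' `std_x <- 1 + (std_x - 1) * exp(-dt / recovery_tau)`.
#'
#' @param syn An [stp_synapse()].
#' @param dt Elapsed time (s), `>= 0`.
#' @param p An [std_params()].
#' @return The updated [stp_synapse()].
#' @export
std_recover <- function(syn, dt, p) {
  if (dt < 0) stop("std_recover: dt must be >= 0")
  b <- syn$std_baseline
  syn$std_x <- b + (syn$std_x - b) * exp(-dt / p$recovery_tau)
  syn
}

#' Route a programmable-synapse contribution to its row integrator
#'
#' Excitatory synapses add the (possibly depressed) EPSC weight to the
#' row's AMPA integrator; inhibitory synapses add the full programmed
#' weight to the row's GABA integrator (the inhibitory branch has no
#' depression circuit).  The neuron's net synaptic input is
#' `i_NMDA (gated) + i_AMPA + i_virt_exc - i_GABA - i_virt_inh`.
#'
#' @param syn An [stp_synapse()].
#' @param epsc_weight EPSC weight from [std_on_pre()] (ignored for
#'   inhibitory synapses).
#' @param w_unit Full-scale weight of the two-bit DAC.
#' @return A list with `target` (`"AMPA_row_dpi"` or `"GABA_row_dpi"`) and
#'   `weight` (non-negative magnitude delivered to that integrator).
#' @export
stp_route_current <- function(syn, epsc_weight = NULL, w_unit = 1) {
  if (syn$is_excitatory) {
    w <- if (is.null(epsc_weight)) base_weight(syn$weight_level, w_unit)
         else epsc_weight
    list(target = "AMPA_row_dpi", weight = w)
  } else {
    list(target = "GABA_row_dpi",
         weight = base_weight(syn$weight_level, w_unit))
  }
}
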