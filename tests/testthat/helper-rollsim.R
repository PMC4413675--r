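# Shared fixtures: small configurations and stimulus builders used across
# the module tests.  Everything is generated in code; no stored data.

# single-neuron chip: one neuron driven through its virtual synapse
single_neuron_cfg <- function(jump_virt = 0.001, ...) {
  chip_config(dpi = list(tau_nmda = 0.1, tau_ampa = 0.02, tau_gaba = 0.02,
                         tau_virt = 0.02, jump_nmda = 1, jump_ampa = 1,
                         jump_gaba = 1, jump_virt = jump_virt), ...)
}

# literal transcription of the weight-update rule, kept independent of
# pre_spike_update(): jump up iff the membrane is high and calcium lies in
# the potentiation window, jump down iff the membrane is low and calcium
# lies in the depression window, otherwise leave the weight alone
ref_update_rule <- function(w, v, ca, p) {
  if (v > p$theta_mem && ca > p$theta1 && ca < p$theta3) {
    w <- w + p$dw_plus
  } else if (v < p$theta_mem && ca > p$theta1 && ca < p$theta2) {
    w <- w - p$dw_minus
  }
  min(max(w, p$w_min), p$w_max)
}

# time-averaged DPI current for a spike train with constant weight,
# accumulated exactly from the piecewise-exponential trajectory
dpi_mean_current <- function(times, weight, tau, jump_scale, t_end) {
  s <- dpi_state(tau = tau, jump_scale = jump_scale)
  t_prev <- 0
  area <- 0
  for (tt in times) {
    dt <- tt - t_prev
    area <- area + s$i_out * tau * (1 - exp(-dt / tau))
    s <- dpi_decay(s, dt)
    s <- dpi_on_spike(s, weight)
    t_prev <- tt
  }
  area <- area + s$i_out * tau * (1 - exp(-(t_end - t_prev) / tau))
  area / t_end
}

test_scenes <- function(seed = 1) {
  ring <- read_edge_map(system.file("extdata", "edge_ring.txt",
                                    package = "rollsim"))
  box <- read_edge_map(system.file("extdata", "edge_box.txt",
                                   package = "rollsim"))
  list(dvs_scene(ring, seed = seed), dvs_scene(box, seed = seed + 50))
}
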