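n_exc_pools: 3.0
exc_pool_size: 64.0
n_inh_pools: 3.0
inh_pool_size: 10.0
p_ee_recurrent: 0.7
p_ii_recurrent: 0.4
p_ee_cross_exc: 0.2
p_ee_cross_inh: 0.2
p_ei: 0.4
p_ie: 0.7
v_in: 100.0
stim_dur: 0.5
reset_rate: 200.0
level_cross_exc: 1.0
level_cross_inh: 3.0
level_ei: 3.0
level_ie: 2.0
gain_nmda: 0.00125
gain_ampa: 0.0125
gain_gaba: 0.02
gain_virt: 0.072
ahp_b: 0.0
ahp_tau: 0.1
inh_leak: 0.15
nmda_gate: no
nmda_gate_threshold: 0.55
seed: 1.0
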