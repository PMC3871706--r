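# Reference circuit: 1000 Purkinje cells, 100 inferior-olive neurons,
# 10:1 climbing-fiber divergence, 800 learning trials.
n_pc: 1000
n_io: 100
divergence: 10
rate_mean: 100.0
rate_sd: 18.0
r_nn: 0.3
pool_size: 20
sigmoid_base: 0.1
sigmoid_amplitude: 0.5
sigmoid_slope: 0.3
sigmoid_midpoint: 100.0
rcs_sd: 0.4
plasticity_amplitude: 5.0
plasticity_decay_step: 2.5
plasticity_mode: additive
n_trials: 800
p_off: 0.5
ev_gain: 0.1
enable_plasticity: true
enable_feedback: true
enable_ss_corr: true
enable_cs_corr: true
renormalize_sd: false
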