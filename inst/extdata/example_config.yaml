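n_sessions: 2
trials_per_session: 80
p_consistent: 0.87
block_len_range: [20, 30]
switches_per_session: 4
seed: 7
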