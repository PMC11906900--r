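# Example pipeline configuration. Every key is optional; omitted keys take
# the reference protocol defaults (see ?load_config).
C: 96
E: [4, 4, 2]
heads: [6, 12, 24, 48]
lr0: 1.0e-4
momentum: 0.99
batch_size: 4
crop: [320, 320, 32]
split: [0.7, 0.1, 0.2]
loss_alpha: 0.5
loss_beta: 0.5
n_subsets: 10
margin: 5
opening_radius: 3
closing_radius: 1
p: 0.1
noise_variance: 0.1
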