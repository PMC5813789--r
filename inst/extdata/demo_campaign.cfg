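# Demo synthetic campaign: two isomorphism groups of four partial sweeps
# each, modest cell (fast to simulate and merge), 6 A data.
seed=101
cell=30,35,40,90,90,90
space_group=P2221
n_groups=2
datasets_per_group=4
group_offset=2
jitter_length=0.2
jitter_angle=0
n_batches=10
coverage=0.3
sweep=random
scale_range=0.5,2
b_range=0,10
sigma0=1
alpha=0.25
mean_intensity=100
d_min=6
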