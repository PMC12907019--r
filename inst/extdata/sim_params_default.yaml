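# Default synthetic-annotation parameters (mirrors sim_params() defaults).
# One merged-style source (M) and two fragment-style sources (F1, F2).
seed: 1
n_elements: {ERV1: 3000, ERV2: 300, ERV3: 6500, Gypsy: 500, Unclassified: 400}
archetype_weights: {fragment: 0.2, solo_ltr: 0.6, provirus: 0.2}
solo_modes: [250, 450]
solo_sds: [40, 60]
fragment_range: [50, 250]
provirus_sdlog: 0.45
frag_prob: 0.3
frag_min_span: 600
frag_extra_mean: 0.6
gap_range: [30, 300]
jitter_sd: 10
shift_prob: 0.02
shift_bp: 300
dropout: {M: 0.02, F1: 0.02, F2: 0.02}
unique_frac: 0.05
short_cutoff: 250
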