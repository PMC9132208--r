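# demo simulation: every planted event type at desk scale, fully seeded
seed = 42
n_l1 = 6
n_duplication_copies = 10
n_bp5 = 4
n_bp3 = 5
n_cassettes = 1
n_flanked_sd = 2
core_duplicon_length = 20000
mu = 0
kappa = 2
tsd_length_range = 8,16
microhomology_range = 1,4
direct_repeat_flank_length = 4000
flank_identity = 1.0
cassette_tsd_length = 12
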