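# Scenario S1: reference synthetic study design.
# 4 expressing vs 4 control samples; 34 canonical histone-like genes in
# multimapping families (true fold change 2.12); 15 variant histone genes
# (true fold change 0.841); 200 unchanging reference candidates; 100 other
# DE genes split half up (fc 2), half down (fc 0.5).
n_case: 4
n_control: 4
n_canonical: 34
canonical_copies: [2, 10]
n_variant: 15
n_unchanging: 200
n_de: 100
fc_canonical: 2.12
fc_variant: 0.841
fc_de_up: 2.0
fc_de_down: 0.5
baseline_mean: 100
baseline_sdlog: 0.8
dispersion: 0.05
library_size: null
read_length: 50
clip_p_enriched: 0.8
clip_p_background: 0.2
seed: 20210101
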