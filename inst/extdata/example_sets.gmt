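cell_cycle	na	gene00001	gene00002	gene00003
dna_repair	na	gene00002	gene00004
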