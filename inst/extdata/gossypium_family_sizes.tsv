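species	n_identified	n_on_scaffolds
A_thaliana	213	0
G_arboreum	298	11
G_barbadense	511	19
G_hirsutum	515	40
G_raimondii	317	4
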