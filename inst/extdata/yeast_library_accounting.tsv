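category	n_knockouts	replicates_each
single	1254	1
duplicate	1910	2
reproducibility_3x	25	3
reproducibility_4x	43	4
reproducibility_5x	1	5
reproducibility_6x	5	6
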