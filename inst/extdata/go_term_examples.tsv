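go_accession	go_name	n_positive_vectors	n_matched_knockouts	n_amigo_genes
GO:0005525	GTP binding	75	45	161
GO:0030529	ribonucleoprotein complex	159	101	868
GO:0008152	metabolic process	393	244	4271
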