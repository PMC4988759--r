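gene_id	s1	s2
g1	10	20
g2	0	5
g3	7	7
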