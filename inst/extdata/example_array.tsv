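array_id	peptide_id	replicate_index	foreground	background
A1	pepA	1	12	2
A1	pepA	2	11.5	2.5
A1	pepB	1	3	10
A1	pepB	2	4	9
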