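source	df	SS	MS	est_var
between_groups	3	243.261	81.087	3.514
within_groups	33	1625.010	49.243	49.243
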