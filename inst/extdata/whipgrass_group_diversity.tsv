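group	h_zone	h_s
GZ	0.3964	0.3621
CQ	0.4921	0.3696
CDP	0.5042	0.3720
YL	0.4136	0.3614
ALL	0.5340	0.3841
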