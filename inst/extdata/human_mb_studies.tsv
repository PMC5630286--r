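study	species	n
mouse	mouse	12
lichter	human	146
parsons	human	53
pugh_cho	human	92
robinson	human	75
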