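element	monoisotopic_mass
H	1.00782503207
C	12.0
N	14.0030740048
O	15.99491461956
S	31.972071
proton	1.00727646677
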